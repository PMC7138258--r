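#' Enumerate the CI sample plan of a dataset
#'
#' The encoding pipeline generates one context image per voxel of five
#' equidistant scan slices per volume; this enumerates those samples (before
#' ROI/background balancing) without simulating anything. A full-scale
#' monospectral training manifest (150 volumes) yields 2,256,000 samples on
#' the default grid; validation/test manifests (25 volumes) yield 376,000.
#'
#' @param dataset a `cepaq_dataset`
#' @param role `"train"`, `"val"` or `"test"`
#' @param n_slices slices per volume
#' @return data.frame with columns `item`, `slice`, `voxel`
#' @export
plan_training_samples <- function(dataset, role = "train", n_slices = 5L) {
  items <- dataset[[role]]
  d <- dataset$grid$dims
  slices <- equidistant_slices(d[3], n_slices)
  nvox <- d[1] * d[2]
  if (!length(items))
    return(data.frame(item = character(), slice = integer(), voxel = integer()))
  ids <- vapply(items, `[[`, "", "id")
  data.frame(
    item = rep(ids, each = length(slices) * nvox),
    slice = rep(rep(slices, each = nvox), times = length(ids)),
    voxel = rep(seq_len(nvox), times = length(ids) * length(slices)))
}

# simulate the five training slices of one item; returns per-slice signal,
# fluence-correction labels and ROI mask
item_slices <- function(item, dataset, setup, phi_h, scale_k, stats,
                        n_photons, noise = 0L, n_slices = 5L) {
  vol <- realize_item(item, dataset)
  d <- dataset$grid$dims
  slices <- equidistant_slices(d[3], n_slices)
  lapply(slices, function(s) {
    mu_a <- vol$mu_a[, , s]
    fl <- simulate_fluence(mu_a, vol$mu_s_prime[, , s], setup, n_photons,
                           seed = derive_seed(item$seed, "mc", s))
    S <- forward_signal(mu_a, fl, scale_k, vol$gamma)
    S_obs <- apply_noise(S, noise, derive_seed(item$seed, "signal", s))
    list(item = item$id, slice = s,
         S = S_obs, S_intrinsic = S,
         phi = fl$phi, phi_c = fl$phi / phi_h$phi,
         roi = roi_mask(vol$labels[, , s], S, stats),
         labels = vol$labels[, , s], mu_a = mu_a)
  })
}

#' Assemble a labeled, class-balanced training set
#'
#' For every manifest item, five equidistant scan slices are simulated at the
#' training photon count; each voxel's context image is the feature and the
#' fluence correction `phi_c = phi / phi_h` the label. Because vessels cover
#' only a small fraction of the image, background voxels are randomly
#' undersampled (seeded, without replacement) to a 1:1 ROI/background ratio;
#' ROI samples are never dropped. Only the selected voxels are encoded.
#'
#' @param dataset a `cepaq_dataset`
#' @param setup a [hardware_setup()]
#' @param bank a `cepaq_fcm_bank` for the setup
#' @param phi_h homogeneous-assumption fluence (`cepaq_fluence`)
#' @param config a [ci_config()]
#' @param scale_k signal scale factor
#' @param stats background `cepaq_bg_stats`
#' @param n_photons photons per training slice
#' @param noise noise level id (applied to the training signals)
#' @param seed balancing seed
#' @param role manifest to use
#' @param balance undersample background to match the ROI count
#' @return `cepaq_training_set`: `features`, `labels`, `roi`, `provenance`,
#'   `config_hash`, `label_type`
#' @export
make_training_set <- function(dataset, setup, bank, phi_h, config, scale_k,
                              stats, n_photons, noise = 0L, seed = 1L,
                              role = "train", balance = TRUE) {
  items <- dataset[[role]]
  if (!length(items)) stop("empty manifest: ", role)
  slabs <- unlist(lapply(items, item_slices, dataset, setup, phi_h, scale_k,
                         stats, n_photons, noise),
                  recursive = FALSE)
  nvox <- prod(dataset$grid$dims[1:2])
  n_roi <- sum(vapply(slabs, function(sl) sum(sl$roi), 0L))
  if (balance && n_roi == 0L)
    stop("no ROI voxels in the whole set: balancing impossible")

  sel <- lapply(seq_along(slabs), function(i) which(slabs[[i]]$roi))
  if (balance) {
    bg_pool_slab <- rep(seq_along(slabs), each = nvox)
    bg_pool_vox <- rep(seq_len(nvox), times = length(slabs))
    is_bg <- !unlist(lapply(slabs, function(sl) as.vector(sl$roi)))
    bg_pool_slab <- bg_pool_slab[is_bg]; bg_pool_vox <- bg_pool_vox[is_bg]
    rng <- local_rng(derive_seed(seed, "balance"))
    take <- order(rng(length(bg_pool_vox)))[seq_len(min(n_roi, length(bg_pool_vox)))]
    for (i in seq_along(slabs))
      sel[[i]] <- sort(c(sel[[i]], bg_pool_vox[take[bg_pool_slab[take] == i]]))
  } else {
    sel <- lapply(seq_along(slabs), function(i) seq_len(nvox))
  }

  feats <- vector("list", length(slabs))
  labs <- roi <- vector("list", length(slabs))
  prov <- vector("list", length(slabs))
  for (i in seq_along(slabs)) {
    sl <- slabs[[i]]
    v <- sel[[i]]
    if (!length(v)) next
    feats[[i]] <- encode_ci_set(sl$S, bank, v, config)
    labs[[i]] <- sl$phi_c[v]
    roi[[i]] <- as.vector(sl$roi)[v]
    prov[[i]] <- data.frame(item = sl$item, slice = sl$slice, voxel = v)
  }
  keep <- !vapply(feats, is.null, TRUE)
  ts <- structure(list(
    features = do.call(rbind, feats[keep]),
    labels = unlist(labs[keep]),
    roi = unlist(roi[keep]),
    provenance = do.call(rbind, prov[keep]),
    config_hash = config$hash,
    label_type = "fluence_correction",
    n_roi = n_roi, seed = seed), class = "cepaq_training_set")
  stopifnot(all(ts$labels > 0))
  ts
}

#' Train the fluence-correction regressor
#'
#' Random forest (default 100 trees, library defaults otherwise) on context
#' image features; the CI configuration hash and label type travel with the
#' model so mismatched features are refused at prediction time.
#'
#' @param training_set a `cepaq_training_set`
#' @param n_trees ensemble size
#' @param seed integer seed
#' @param ... passed to [rf_fit()]
#' @export
train_regressor <- function(training_set, n_trees = 100L, seed = 1L, ...) {
  if (!nrow(training_set$features)) stop("empty training set")
  rf <- rf_fit(training_set$features, training_set$labels,
               n_trees = n_trees, seed = seed, ...)
  structure(list(rf = rf, config_hash = training_set$config_hash,
                 label_type = training_set$label_type),
            class = "cepaq_fluence_model")
}

#' Predict fluence from context images
#'
#' The model predicts the fluence correction `phi_c`; the fluence estimate is
#' `phi_hat = phi_c_hat * phi_h` at the voxel.
#'
#' @param model a `cepaq_fluence_model`
#' @param features CI feature matrix from [encode_ci_set()] (its config hash
#'   must match the model's)
#' @param phi_h_at_voxel homogeneous fluence at the encoded voxels
#' @return fluence estimates, strictly positive
#' @export
predict_fluence <- function(model, features, phi_h_at_voxel) {
  stopifnot(model$label_type == "fluence_correction")
  h <- attr(features, "config_hash")
  if (!is.null(h) && !identical(h, model$config_hash))
    stop("CI configuration hash mismatch between features and model; ",
         "refusing to predict on drifted feature layout")
  phi_c <- predict(model$rf, features)
  phi_c * phi_h_at_voxel
}

#' Predict the fluence map of a whole slice
#'
#' Encodes every plane voxel of the signal slice and applies
#' [predict_fluence()].
#'
#' @param model a `cepaq_fluence_model`
#' @param S signal slice
#' @param bank FCM bank
#' @param phi_h homogeneous fluence (`cepaq_fluence`)
#' @param config the [ci_config()] used in training
#' @export
predict_fluence_slice <- function(model, S, bank, phi_h, config) {
  feats <- encode_ci_set(S, bank, NULL, config)
  phi_hat <- predict_fluence(model, feats, as.vector(phi_h$phi))
  matrix(phi_hat, nrow = nrow(S))
}

#' Reconstruct optical absorption from signal and estimated fluence
#'
#' Inverts the signal model: `mu_a_hat = S / (k * Gamma * phi_hat)`. Voxels
#' whose signal hit the clip bound are flagged in the `clipped` attribute
#' (their absorption is a lower bound only).
#'
#' @param S signal slice (with optional `clipped` attribute from
#'   [forward_signal()])
#' @param phi_hat fluence estimate, must be positive everywhere
#' @param scale_k signal scale factor
#' @param gamma Grueneisen coefficient
#' @export
reconstruct_absorption <- function(S, phi_hat, scale_k, gamma = 1) {
  if (inherits(phi_hat, "cepaq_fluence")) phi_hat <- phi_hat$phi
  if (!identical(dim(S), dim(phi_hat))) stop("signal and fluence grids differ")
  if (any(phi_hat <= 0)) stop("non-positive fluence estimate")
  mu <- unclass(S) / (scale_k * gamma * phi_hat)
  attributes(mu) <- list(dim = dim(phi_hat))
  attr(mu, "clipped") <- attr(S, "clipped") %||% (S >= 255)
  mu
}
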