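#' Relative fluence estimation error
#'
#' `er(v) = |phi_hat(v) - phi(v)| / phi(v)`, elementwise. Voxels with
#' `phi = 0` are excluded (their count is reported in the `n_excluded`
#' attribute); it is an error if no voxel remains.
#'
#' @param phi_hat fluence estimate
#' @param phi reference fluence
#' @return er values (vector, excluded voxels dropped)
#' @export
relative_fluence_error <- function(phi_hat, phi) {
  if (inherits(phi_hat, "cepaq_fluence")) phi_hat <- phi_hat$phi
  if (inherits(phi, "cepaq_fluence")) phi <- phi$phi
  stopifnot(length(phi_hat) == length(phi))
  ok <- phi > 0
  if (!any(ok)) stop("all voxels have zero reference fluence")
  er <- abs(phi_hat[ok] - phi[ok]) / phi[ok]
  attr(er, "n_excluded") <- sum(!ok)
  er
}

#' Median and interquartile range of an error sample
#'
#' Linear-interpolation (type 7) quantiles.
#'
#' @param values numeric vector, non-empty
#' @return list with `median`, `q1`, `q3`, `n`
#' @export
summarize_error <- function(values) {
  if (!length(values)) stop("empty error sample")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Benchmark presets
#'
#' Reduced-scale presets trade Monte Carlo fidelity and dataset size for
#' runtime; expected errors inflate accordingly relative to full scale.
#' * `smoke`: 32 x 24 x 16 grid, 5 training volumes, 1e4 photons/slice,
#'   200-hit FCMs -- seconds-to-minutes, for tests and demos.
#' * `bench`: full grid, 12 training volumes, 1e5 photons/slice training,
#'   1e6 test, 500-hit FCMs -- intermediate scale.
#' * `desk`: full grid, 40 training volumes, 1e5 photons/slice training,
#'   2e6 test, 2000-hit FCMs -- the scale used by the acceptance checks;
#'   expect inflated errors relative to full scale (see vignette).
#' * `paper`: full experimental scale (150/25/25 volumes, 2e6 photons per
#'   training slice, 1e8 per test slice, 1e4-hit FCMs) -- hours to days.
#'
#' @param name preset name
#' @export
bench_preset <- function(name = c("smoke", "bench", "desk", "paper")) {
  name <- match.arg(name)
  p <- switch(name,
    smoke = list(dims = c(32L, 24L, 16L), n_train = 5L, n_val = 2L,
                 n_test = 2L, photons_train = 1e4, photons_test = 1e5,
                 photons_phih = 2e5, fcm_min_hits = 200, fcm_batch = 2e4,
                 fcm_max_batches = 400L, n_trees = 100L,
                 oxy_n_train = 8L, oxy_n_test = 3L,
                 oxy_photons_train = 1e4, oxy_photons_test = 1e5,
                 oxy_max_samples = 4000, mip_axis = "z"),
    bench = list(dims = c(64L, 47L, 62L), n_train = 12L, n_val = 0L,
                 n_test = 3L, photons_train = 1e5, photons_test = 1e6,
                 photons_phih = 4e6, fcm_min_hits = 500, fcm_batch = 1e5,
                 fcm_max_batches = 400L, n_trees = 100L,
                 oxy_n_train = 30L, oxy_n_test = 11L,
                 oxy_photons_train = 1e5, oxy_photons_test = 4e5,
                 oxy_max_samples = 16000, mip_axis = "z"),
    desk = list(dims = c(64L, 47L, 62L), n_train = 40L, n_val = 5L,
                n_test = 3L, photons_train = 1e5, photons_test = 1e6,
                photons_phih = 1e7, fcm_min_hits = 2000, fcm_batch = 2e5,
                fcm_max_batches = 500L, n_trees = 100L,
                oxy_n_train = 40L, oxy_n_test = 11L,
                oxy_photons_train = 1e5, oxy_photons_test = 4e5,
                oxy_max_samples = 12000, mip_axis = "z"),
    paper = list(dims = c(64L, 47L, 62L), n_train = NULL, n_val = NULL,
                 n_test = NULL, photons_train = 2e6, photons_test = 1e8,
                 photons_phih = 1e8, fcm_min_hits = 1e4, fcm_batch = 1e6,
                 fcm_max_batches = 1000L, n_trees = 100L,
                 oxy_n_train = 240L, oxy_n_test = 11L,
                 oxy_photons_train = 1e7, oxy_photons_test = 1e7,
                 oxy_max_samples = Inf, mip_axis = "z"))
  structure(c(list(name = name), p), class = "cepaq_preset")
}

#' Prepare the per-setup context shared by all experiments
#'
#' Everything tied to the hardware setup and independent of the dataset:
#' homogeneous-assumption fluence, signal-scale calibration and background
#' statistics, the FCM bank, and the CI configuration. Computing this once
#' and passing it to [run_experiment()] reuses the (expensive) FCM bank
#' across datasets and noise levels.
#'
#' @param preset a [bench_preset()] (or its name)
#' @param seed master seed
#' @param config a [ci_config()]
#' @export
prepare_context <- function(preset, seed, config = ci_config()) {
  if (is.character(preset)) preset <- bench_preset(preset)
  setup <- hardware_setup(grid_spec(preset$dims))
  phi_h <- homogeneous_fluence(setup, preset$photons_phih,
                               derive_seed(seed, "phi_h"))
  phi_bg <- homogeneous_fluence(setup, preset$photons_train,
                                derive_seed(seed, "background"))
  cal <- calibrate_scale_k(setup, phi = phi_bg)
  bank <- precompute_fcm_bank(setup, preset$fcm_min_hits,
                              seed = derive_seed(seed, "fcm"),
                              batch_photons = preset$fcm_batch,
                              max_batches = preset$fcm_max_batches)
  structure(list(preset = preset, seed = seed, setup = setup, phi_h = phi_h,
                 scale_k = cal$scale_k, stats = cal$stats, bank = bank,
                 config = config), class = "cepaq_context")
}

# evaluate one dataset's test items; returns pooled er strata for the
# context-encoding estimate and the static phi_h baseline
evaluate_testset <- function(ds, ctx, model, noise) {
  preset <- ctx$preset
  er_ce <- er_h <- list(all = numeric(), roi = numeric())
  n_clip <- 0L
  for (item in ds$test) {
    slabs <- item_slices(item, ds, ctx$setup, ctx$phi_h, ctx$scale_k,
                         ctx$stats, preset$photons_test, noise)
    for (sl in slabs) {
      phi_hat <- predict_fluence_slice(model, sl$S, ctx$bank, ctx$phi_h,
                                       ctx$config)
      er1 <- relative_fluence_error(phi_hat, sl$phi)
      er0 <- relative_fluence_error(ctx$phi_h$phi, sl$phi)
      roi <- as.vector(sl$roi)[sl$phi > 0]
      er_ce$all <- c(er_ce$all, er1); er_ce$roi <- c(er_ce$roi, er1[roi])
      er_h$all <- c(er_h$all, er0);  er_h$roi <- c(er_h$roi, er0[roi])
    }
  }
  list(ce = er_ce, baseline = er_h)
}

#' Run a monospectral fluence-estimation experiment
#'
#' Generates the dataset at the preset's scale, trains the fluence-correction
#' forest on the training manifest, and evaluates the relative fluence error
#' on the (never before touched) test manifest, pooled over voxels, both over
#' all voxels and restricted to the ROI; the static homogeneous correction
#' (`phi_hat = phi_h`) is evaluated as baseline on the same voxels.
#' Summaries are reported in percent.
#'
#' @param ds_name dataset design name (see [dataset_spec()])
#' @param preset a [bench_preset()] or its name
#' @param noise noise level id 0-3 (applied to training and test signals)
#' @param seed master seed; identical seeds and configuration reproduce the
#'   report byte for byte
#' @param context optional [prepare_context()] result to reuse
#' @return `cepaq_report` list
#' @export
run_experiment <- function(ds_name = "DSbase", preset = "smoke", noise = 0L,
                           seed = 1L, context = NULL) {
  ctx <- context %||% prepare_context(preset, seed)
  preset <- ctx$preset
  spec <- dataset_spec(ds_name, n_train = preset$n_train,
                       n_val = preset$n_val, n_test = preset$n_test)
  ds <- build_dataset(spec, derive_seed(seed, "ds", ds_name),
                      grid = ctx$setup$grid)
  ts <- make_training_set(ds, ctx$setup, ctx$bank, ctx$phi_h, ctx$config,
                          ctx$scale_k, ctx$stats, preset$photons_train,
                          noise = noise, seed = derive_seed(seed, "balance"))
  model <- train_regressor(ts, n_trees = preset$n_trees,
                           seed = derive_seed(seed, "forest"))
  ev <- evaluate_testset(ds, ctx, model, noise)
  pct <- function(er) {
    s <- summarize_error(er * 100)
    s[c("median", "q1", "q3", "n")]
  }
  structure(list(
    dataset = ds_name, preset = preset$name, noise = noise, seed = seed,
    ci_counts = list(train = nrow(plan_training_samples(ds, "train")),
                     val = nrow(plan_training_samples(ds, "val")),
                     test = nrow(plan_training_samples(ds, "test"))),
    n_training_samples = nrow(ts$features),
    er = list(ce = list(all = pct(ev$ce$all), roi = pct(ev$ce$roi)),
              baseline = list(all = pct(ev$baseline$all),
                              roi = pct(ev$baseline$roi))),
    hashes = list(setup = ctx$setup$hash, ci_config = ctx$config$hash)),
    class = "cepaq_report")
}

#' Run the multispectral oxygenation experiment
#'
#' Generates the oxygenation phantom set at the preset's scale (training
#' volumes with sO2 ~ U(0, 1), test volumes on the fixed sO2 ladder), trains
#' one fluence-correction forest per wavelength plus the functional
#' (sO2-labeled, concatenated-CI) forest, and compares three estimators on
#' the vessel voxels selected by the 800 nm maximum intensity projection:
#' raw-signal unmixing, fluence-corrected unmixing, and direct functional
#' regression. Reports median absolute sO2 error (in percentage points) per
#' method.
#'
#' @inheritParams run_experiment
#' @export
run_oxy_experiment <- function(preset = "smoke", seed = 1L, context = NULL) {
  ctx <- context %||% prepare_context(preset, seed)
  preset <- ctx$preset
  wavelengths <- c(750, 800, 850)
  wl_key <- as.character(wavelengths)
  A <- reference_spectra(wavelengths)
  model <- blood_optics()
  spec <- dataset_spec("DSoxy", n_train = preset$oxy_n_train,
                       n_test = preset$oxy_n_test)
  ds <- build_dataset(spec, derive_seed(seed, "ds", "DSoxy"),
                      grid = ctx$setup$grid)
  d <- ctx$setup$grid$dims
  nvox <- d[1] * d[2]

  sim_item <- function(item, n_photons) {
    vol <- realize_item(item, ds)
    slices <- equidistant_slices(d[3], 5L)
    lapply(slices, function(s) {
      out <- list(slice = s, so2 = item$so2, labels = vol$labels[, , s])
      for (w in wl_key) {
        mu_a <- optics_at_wavelength(vol, as.numeric(w), model)[, , s]
        fl <- simulate_fluence(mu_a, vol$mu_s_prime[, , s], ctx$setup,
                               n_photons, derive_seed(item$seed, "mc", s, w))
        out$S[[w]] <- forward_signal(mu_a, fl, ctx$scale_k, vol$gamma)
        out$phi[[w]] <- fl$phi
        out$phi_c[[w]] <- fl$phi / ctx$phi_h$phi
      }
      out$roi <- roi_mask(out$labels, out$S[["800"]], ctx$stats)
      out
    })
  }

  # ---- training --------------------------------------------------------
  slabs <- unlist(lapply(ds$train, sim_item, preset$oxy_photons_train),
                  recursive = FALSE)
  n_roi <- sum(vapply(slabs, function(sl) sum(sl$roi), 0L))
  if (n_roi == 0L) stop("no ROI voxels in the oxygenation training set")
  rng <- local_rng(derive_seed(seed, "oxy-balance"))
  is_bg <- !unlist(lapply(slabs, function(sl) as.vector(sl$roi)))
  n_take <- min(n_roi, sum(is_bg))
  cap <- preset$oxy_max_samples %||% Inf
  if (is.finite(cap) && 2 * n_take > cap) {
    # runtime cap: subsample ROI and background equally, preserving the 1:1
    # ratio (a scale reduction, see the methods vignette)
    n_take <- floor(cap / 2)
    roi_idx <- which(!is_bg)
    roi_keep <- roi_idx[order(rng(length(roi_idx)))[seq_len(n_take)]]
  } else {
    roi_keep <- which(!is_bg)
  }
  take <- which(is_bg)[order(rng(sum(is_bg)))[seq_len(n_take)]]
  keep <- sort(c(roi_keep, take))
  slab_of <- (keep - 1L) %/% nvox + 1L
  vox_of <- (keep - 1L) %% nvox + 1L

  feats_wl <- list()
  for (w in wl_key) {
    fw <- vector("list", length(slabs))
    for (i in seq_along(slabs)) {
      v <- vox_of[slab_of == i]
      if (length(v))
        fw[[i]] <- encode_ci_set(slabs[[i]]$S[[w]], ctx$bank, v, ctx$config)
    }
    feats_wl[[w]] <- do.call(rbind, fw[!vapply(fw, is.null, TRUE)])
  }
  lab_phi_c <- lapply(wl_key, function(w)
    unlist(lapply(seq_along(slabs), function(i) {
      v <- vox_of[slab_of == i]
      slabs[[i]]$phi_c[[w]][v]
    })))
  names(lab_phi_c) <- wl_key
  lab_so2 <- unlist(lapply(seq_along(slabs), function(i)
    rep(slabs[[i]]$so2, sum(slab_of == i))))

  fl_models <- lapply(wl_key, function(w) {
    ts <- structure(list(features = feats_wl[[w]], labels = lab_phi_c[[w]],
                         config_hash = ctx$config$hash,
                         label_type = "fluence_correction"),
                    class = "cepaq_training_set")
    train_regressor(ts, n_trees = preset$n_trees,
                    seed = derive_seed(seed, "forest", w))
  })
  names(fl_models) <- wl_key
  fn_model <- structure(list(
    rf = rf_fit(do.call(cbind, feats_wl[wl_key]), lab_so2,
                n_trees = preset$n_trees,
                seed = derive_seed(seed, "forest", "functional")),
    config_hash = ctx$config$hash, label_type = "so2"),
    class = "cepaq_fluence_model")

  # ---- testing ---------------------------------------------------------
  err <- list(raw_unmix = numeric(), ce_unmix = numeric(),
              functional = numeric())
  for (item in ds$test) {
    for (sl in sim_item(item, preset$oxy_photons_test)) {
      mip <- mip_select(sl$S[["800"]], preset$mip_axis %||% "z")
      eval_idx <- mip[as.vector(sl$labels)[mip] > 0]   # vessel MIP voxels
      if (!length(eval_idx)) next
      fw <- lapply(wl_key, function(w)
        encode_ci_set(sl$S[[w]], ctx$bank, eval_idx, ctx$config))
      names(fw) <- wl_key
      phi_hat <- lapply(wl_key, function(w) {
        ph <- rep(NA_real_, nvox)
        ph[eval_idx] <- predict_fluence(fl_models[[w]], fw[[w]],
                                        as.vector(ctx$phi_h$phi)[eval_idx])
        ph
      })
      names(phi_hat) <- wl_key
      est <- list(
        raw_unmix = estimate_so2("raw_unmix", sl$S, eval_idx, A),
        ce_unmix = estimate_so2("ce_unmix", sl$S, eval_idx, A,
                                scale_k = ctx$scale_k, phi_hat = phi_hat),
        functional = estimate_so2("functional", sl$S, eval_idx, A,
                                  model = fn_model,
                                  features = do.call(cbind, fw[wl_key])))
      for (m in names(err)) {
        e <- abs(est[[m]]$so2 - sl$so2)
        err[[m]] <- c(err[[m]], e[!is.na(e)])
      }
    }
  }

  pct <- function(e) {
    s <- summarize_error(e * 100)
    s[c("median", "q1", "q3", "n")]
  }
  structure(list(
    dataset = "DSoxy", preset = preset$name, seed = seed,
    wavelengths = wavelengths,
    so2_error = lapply(err, pct),
    n_training_samples = nrow(feats_wl[[1]]),
    hashes = list(setup = ctx$setup$hash, ci_config = ctx$config$hash)),
    class = "cepaq_report")
}

#' Serialize a report deterministically to JSON
#'
#' Identical reports (same seeds, same configuration) serialize to identical
#' bytes, which is how end-to-end determinism is asserted.
#'
#' @param report a `cepaq_report`
#' @param path optional file to write
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}
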