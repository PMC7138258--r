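#' Illumination source specification
#'
#' The reference hardware is a linear-probe style setup where detector and
#' illumination move together, so illumination is identical for every slice.
#' Default is a collimated line source spanning the full lateral width of the
#' imaging plane at the tissue surface (z = 0), pointing into depth. A pencil
#' beam and a finite slab are available for validation work.
#'
#' @param type `"line"`, `"pencil"` or `"slab"`
#' @param position lateral position in mm (pencil; default = plane center)
#' @param x0,x1 slab extent in mm
#' @export
source_spec <- function(type = c("line", "pencil", "slab"),
                        position = NULL, x0 = NULL, x1 = NULL) {
  type <- match.arg(type)
  structure(list(type = type, position = position, x0 = x0, x1 = x1),
            class = "cepaq_source")
}

source_params <- function(source, grid) {
  width <- grid$dims[1] * grid$spacing
  switch(source$type,
    pencil = list(code = 0L, x0 = source$position %||% (width / 2), x1 = 0),
    line   = list(code = 1L, x0 = 0, x1 = width),
    slab   = list(code = 2L, x0 = source$x0 %||% 0, x1 = source$x1 %||% width))
}

#' Hardware setup: grid, illumination and homogeneous background assumption
#'
#' Everything that is fixed per device: the voxel grid, the source geometry,
#' and the background optical properties (absorption 0.1 cm^-1, reduced
#' scattering 1.5 cm^-1) used for the homogeneous-assumption fluence and the
#' fluence contribution maps. Scattering is simulated isotropically with
#' `mu_s = mu_s' / (1 - g)` (similarity relation); `g = 0` by default since
#' fluence fields depend on `mu_s'` to first order.
#'
#' @param grid a [grid_spec()]
#' @param source a [source_spec()]
#' @param bg_mu_a background absorption, cm^-1
#' @param bg_mu_s_prime background reduced scattering, cm^-1
#' @param g scattering anisotropy used by the similarity relation
#' @export
hardware_setup <- function(grid = grid_spec(), source = source_spec("line"),
                           bg_mu_a = 0.1, bg_mu_s_prime = 1.5, g = 0) {
  stopifnot(g >= 0, g < 1)
  s <- structure(list(grid = grid, source = source, bg_mu_a = bg_mu_a,
                      bg_mu_s_prime = bg_mu_s_prime, g = g),
                 class = "cepaq_setup")
  s$hash <- config_hash(unclass(s))
  s
}

# cm^-1 -> mm^-1 plus the similarity relation for scattering
transport_coeffs <- function(mu_a, mu_s_prime, g) {
  list(mu_a = mu_a * 0.1, mu_s = mu_s_prime * 0.1 / (1 - g))
}

#' Simulate light fluence on one imaging-plane slice
#'
#' Voxel-grid Monte Carlo: photon packets are launched from the source,
#' propagated with exponentially sampled free paths and isotropic scattering,
#' attenuated by the albedo at each collision, and terminated by Russian
#' roulette below weight 1e-4 (survival probability 0.1). Fluence is scored
#' per voxel and normalized per launched photon (arbitrary units; all
#' downstream quantities are ratios or are calibrated by `scale_k`).
#'
#' Two estimators are available. `"track"` (default) scores
#' `weight x path length / voxel area` and is defined for any `mu_a`
#' including 0; `"deposition"` scores collision deposits
#' `/ (mu_a x voxel area)` and falls back to the track-length value in
#' voxels with `mu_a = 0`.
#'
#' @param mu_a,mu_s_prime absorption / reduced scattering slice matrices
#'   (lateral x depth), cm^-1
#' @param setup a [hardware_setup()] (grid spacing + source are used)
#' @param n_photons photons to launch
#' @param seed integer seed (bit-for-bit reproducible)
#' @param n_batches batches used for the per-voxel standard error estimate
#' @param estimator `"track"` or `"deposition"`
#' @return `cepaq_fluence`: list with `phi`, `se`, `ledger`, `n_photons`,
#'   `seed`, `estimator`
#' @export
simulate_fluence <- function(mu_a, mu_s_prime, setup, n_photons, seed,
                             n_batches = 10L,
                             estimator = c("track", "deposition")) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(mu_a), identical(dim(mu_a), dim(mu_s_prime)),
            n_photons >= 1)
  tc <- transport_coeffs(mu_a, mu_s_prime, setup$g)
  if (estimator == "deposition" && all(tc$mu_a + tc$mu_s == 0))
    stop("all-zero attenuation: no interactions possible under deposition ",
         "scoring; use the track-length estimator")
  sp <- source_params(setup$source, setup$grid)
  res <- mc_fluence_cpp(tc$mu_a, tc$mu_s, setup$grid$spacing,
                        sp$code, sp$x0, sp$x1,
                        as.double(n_photons), as.integer(n_batches),
                        as.integer(seed))
  phi <- res$phi_track
  if (estimator == "deposition") {
    h2 <- setup$grid$spacing^2
    dep <- res$deposit / (tc$mu_a * h2 * n_photons)
    use <- tc$mu_a > 0
    phi[use] <- dep[use]
  }
  structure(list(phi = phi, se = res$phi_se, deposit = res$deposit,
                 ledger = res$ledger, n_photons = n_photons, seed = seed,
                 estimator = estimator),
            class = "cepaq_fluence")
}

#' Homogeneous-assumption fluence phi_h
#'
#' [simulate_fluence()] on a uniform slice with the setup's background
#' properties. Computed once per hardware setup at high photon count and
#' reused for training labels, prediction and the static correction baseline.
#'
#' @inheritParams simulate_fluence
#' @export
homogeneous_fluence <- function(setup, n_photons, seed, n_batches = 10L) {
  d <- setup$grid$dims
  mu_a <- matrix(setup$bg_mu_a, d[1], d[2])
  mu_s <- matrix(setup$bg_mu_s_prime, d[1], d[2])
  simulate_fluence(mu_a, mu_s, setup, n_photons, seed, n_batches)
}

#' Fluence contribution map for a single target voxel
#'
#' Photons are launched in batches through the homogeneous background medium
#' until at least `min_target_hits` distinct photons have traversed the
#' target voxel. `FCM[v](v')` is the fraction of those photons that also
#' traversed `v'` (each photon counted at most once per voxel), so
#' `FCM[v](v) = 1` and all values lie in `[0, 1]`.
#'
#' @param target target voxel, either a linear plane index or `c(ix, iz)`
#' @param setup a [hardware_setup()]
#' @param min_target_hits hit quota in the target voxel
#' @param seed integer seed
#' @param batch_photons photons per batch
#' @param max_batches batch cap; an unreachable quota is an error that
#'   reports the achieved hit count
#' @return `cepaq_fcm`: list with `fcm` (lateral x depth matrix), `hits`,
#'   `photons`, `target`
#' @export
simulate_fcm <- function(target, setup, min_target_hits = 1e4, seed = 1L,
                         batch_photons = 1e5, max_batches = 100L) {
  d <- setup$grid$dims
  nx <- d[1]; nz <- d[2]
  if (length(target) == 2L) target <- (target[1] - 1L) + nx * (target[2] - 1L)
  else target <- as.integer(target) - 1L
  stopifnot(target >= 0, target < nx * nz, min_target_hits >= 1)
  tc <- transport_coeffs(setup$bg_mu_a, setup$bg_mu_s_prime, setup$g)
  sp <- source_params(setup$source, setup$grid)
  res <- mc_fcm_cpp(as.integer(target), tc$mu_a, tc$mu_s, nx, nz,
                    setup$grid$spacing, sp$code, sp$x0, sp$x1,
                    as.integer(min_target_hits), as.double(batch_photons),
                    as.integer(max_batches), as.integer(seed))
  if (res$hits < min_target_hits)
    stop("FCM hit quota unreachable within the batch cap: achieved ",
         res$hits, " of ", min_target_hits, " hits")
  structure(list(fcm = res$fcm, hits = res$hits, photons = res$photons,
                 target = target + 1L),
            class = "cepaq_fcm")
}

#' Precompute the fluence-contribution-map bank for a hardware setup
#'
#' One FCM per imaging-plane voxel, computed in a single shared photon pass
#' (pairwise traversal counts accumulate for all targets at once; the
#' estimator is identical to [simulate_fcm()]). Photon batches continue until
#' the worst-covered plane voxel reaches `min_target_hits`. The bank is tied
#' to the setup by its configuration hash; [load_fcm_bank()] refuses a bank
#' whose hash does not match.
#'
#' @inheritParams simulate_fcm
#' @param cache_file optional RDS path; if it exists and matches the setup
#'   hash the bank is loaded instead of recomputed
#' @return `cepaq_fcm_bank`: `bank` is an `nvox x nvox` matrix whose column
#'   `v` is `FCM[v]` over the plane
#' @export
precompute_fcm_bank <- function(setup, min_target_hits = 1e4, seed = 1L,
                                batch_photons = 1e5, max_batches = 100L,
                                cache_file = NULL) {
  if (!is.null(cache_file) && file.exists(cache_file))
    return(load_fcm_bank(cache_file, setup))
  d <- setup$grid$dims
  tc <- transport_coeffs(setup$bg_mu_a, setup$bg_mu_s_prime, setup$g)
  sp <- source_params(setup$source, setup$grid)
  res <- mc_fcm_bank_cpp(tc$mu_a, tc$mu_s, d[1], d[2], setup$grid$spacing,
                         sp$code, sp$x0, sp$x1,
                         as.integer(min_target_hits),
                         as.double(batch_photons), as.integer(max_batches),
                         as.integer(seed))
  if (res$min_hits_achieved < min_target_hits)
    stop("FCM bank hit quota unreachable within the batch cap: worst voxel ",
         "achieved ", res$min_hits_achieved, " of ", min_target_hits, " hits")
  bank <- structure(list(bank = res$bank, hits = res$hits,
                         photons = res$photons, nx = d[1], nz = d[2],
                         min_target_hits = min_target_hits, seed = seed,
                         setup_hash = setup$hash),
                    class = "cepaq_fcm_bank")
  if (!is.null(cache_file)) saveRDS(bank, cache_file)
  bank
}

#' Load a cached FCM bank, verifying the hardware-setup hash
#'
#' @param path RDS file written by [precompute_fcm_bank()]
#' @param setup the [hardware_setup()] the bank must match
#' @export
load_fcm_bank <- function(path, setup) {
  bank <- readRDS(path)
  if (!identical(bank$setup_hash, setup$hash))
    stop("FCM bank at ", path, " was computed for a different hardware ",
         "setup (hash mismatch); refusing to use it")
  bank
}
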