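#' Photoacoustic signal formation
#'
#' The measured signal is proportional to the absorbed energy:
#' `S = clip(k * mu_a * Gamma * phi, 0, 255)`. The global proportionality
#' constant `k` is a hardware property (see [calibrate_scale_k()]); values
#' are clipped at the 255 a.u. ceiling of the signal dynamic range rather
#' than rescaled per image, so context images stay comparable across images.
#' The result is continuous (not quantized).
#'
#' @param mu_a absorption slice, cm^-1
#' @param phi fluence slice (matrix or `cepaq_fluence`)
#' @param scale_k global scale factor, a.u. per (cm^-1 x fluence unit)
#' @param gamma Grueneisen coefficient (scalar or matrix)
#' @param clip upper signal bound in a.u.
#' @return signal matrix in a.u. with attribute `clipped` (logical matrix)
#' @export
forward_signal <- function(mu_a, phi, scale_k, gamma = 1, clip = 255) {
  if (inherits(phi, "cepaq_fluence")) phi <- phi$phi
  if (!identical(dim(mu_a), dim(phi)))
    stop("absorption and fluence grids differ")
  stopifnot(scale_k > 0)
  raw <- scale_k * mu_a * gamma * phi
  S <- pmin(pmax(raw, 0), clip)
  attr(S, "clipped") <- raw > clip
  S
}

#' Three-level signal noise model
#'
#' Level 0 is the simulation-intrinsic case (no added noise). Levels 1-3 add
#' an additive Gaussian term followed by a multiplicative white Gaussian
#' term: 2% multiplicative with (0.125 +/- 0.125) a.u. additive, 10% with
#' (0.625 +/- 0.625), and 20% with (1.25 +/- 1.25).
#'
#' @param level 0, 1, 2 or 3
#' @return list with `level`, `mult_sd`, `add_mean`, `add_sd`
#' @export
noise_level <- function(level) {
  stopifnot(level %in% 0:3)
  params <- list(
    list(level = 0L, mult_sd = 0,    add_mean = 0,     add_sd = 0),
    list(level = 1L, mult_sd = 0.02, add_mean = 0.125, add_sd = 0.125),
    list(level = 2L, mult_sd = 0.10, add_mean = 0.625, add_sd = 0.625),
    list(level = 3L, mult_sd = 0.20, add_mean = 1.25,  add_sd = 1.25))
  params[[level + 1L]]
}

#' Apply the noise model to a signal slice or volume
#'
#' `S' = (S + A) * (1 + M)` with `A ~ N(add_mean, add_sd)` and
#' `M ~ N(0, mult_sd)`, additive before multiplicative; negative results are
#' clipped to zero. Level 0 is the identity.
#'
#' @param S signal array, a.u.
#' @param level noise level id (0-3) or a [noise_level()] list
#' @param seed integer seed
#' @export
apply_noise <- function(S, level, seed) {
  if (!is.list(level)) level <- noise_level(level)
  if (level$level == 0L) return(S)
  rng <- local_rng(derive_seed(seed, "noise", level$level))
  n <- length(S)
  A <- stats::qnorm(rng(n), level$add_mean, level$add_sd)
  M <- stats::qnorm(rng(n), 0, level$mult_sd)
  out <- pmax((S + A) * (1 + M), 0)
  dim(out) <- dim(S)
  out
}

#' Intrinsic background signal statistics
#'
#' Mean and standard deviation of the signal over a simulated homogeneous
#' background slice (absorption 0.1 cm^-1, no structures, no added noise);
#' the spread combines depth decay of the fluence with Monte Carlo noise.
#' These statistics anchor the contrast-to-noise ratio.
#'
#' @param setup a [hardware_setup()]
#' @param scale_k signal scale factor
#' @param n_photons photons for the background simulation
#' @param seed integer seed
#' @param phi optional precomputed background `cepaq_fluence` (skips the
#'   simulation)
#' @return `cepaq_bg_stats`: list with `avg`, `std`, `n_photons`, `seed`
#' @export
background_stats <- function(setup, scale_k, n_photons = 1e6, seed = 1L,
                             phi = NULL) {
  if (is.null(phi)) phi <- homogeneous_fluence(setup, n_photons, seed)
  S <- forward_signal(matrix(setup$bg_mu_a, setup$grid$dims[1], setup$grid$dims[2]),
                      phi, scale_k)
  std <- stats::sd(S)
  if (!is.finite(std) || std <= 0)
    stop("degenerate background slice: std(b) = 0, CNR undefined")
  structure(list(avg = mean(S), std = std,
                 n_photons = phi$n_photons, seed = phi$seed),
            class = "cepaq_bg_stats")
}

#' Calibrate the global signal scale k
#'
#' `k` is chosen once per hardware setup so that the homogeneous background
#' slice (0.1 cm^-1) has mean signal 4.2 a.u., anchoring the `[0, 255]`
#' dynamic range to the measured intrinsic background statistics.
#'
#' @inheritParams background_stats
#' @param target_mean desired mean background signal, a.u.
#' @return list with `scale_k`, `stats` (a `cepaq_bg_stats`), and the
#'   background fluence used
#' @export
calibrate_scale_k <- function(setup, n_photons = 1e6, seed = 1L,
                              target_mean = 4.2, phi = NULL) {
  if (is.null(phi)) phi <- homogeneous_fluence(setup, n_photons, seed)
  base <- mean(setup$bg_mu_a * phi$phi)
  stopifnot(base > 0)
  k <- target_mean / base
  list(scale_k = k, stats = background_stats(setup, k, phi = phi), phi = phi)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (S - avg(b)) / std(b)`, signed, against the intrinsic background
#' statistics of the setup.
#'
#' @param S signal value(s), a.u.
#' @param stats a `cepaq_bg_stats`
#' @export
compute_cnr <- function(S, stats) {
  if (stats$std <= 0) stop("std(b) must be positive")
  (S - stats$avg) / stats$std
}

#' Region-of-interest mask
#'
#' ROI voxels are vessel voxels whose signal has CNR strictly greater
#' than 2; the ROI is always a subset of the vessel label set.
#'
#' @param labels vessel label slice (0 = background)
#' @param S signal slice, a.u.
#' @param stats a `cepaq_bg_stats`
#' @return logical mask
#' @export
roi_mask <- function(labels, S, stats) {
  if (!identical(dim(labels), dim(S))) stop("label and signal grids differ")
  labels > 0 & compute_cnr(S, stats) > 2
}
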