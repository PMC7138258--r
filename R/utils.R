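#' Derive a child seed from a parent seed and a label path
#'
#' All randomness in cepaq is funnelled through one seed hierarchy
#' (dataset seed -> item seed -> Monte Carlo seed -> noise seed -> balancing
#' seed). Children are derived by hashing the parent seed together with a
#' label path, so independent stages get independent, reproducible streams.
#'
#' @param seed parent integer seed
#' @param ... labels (coerced to character) identifying the child stream
#' @return an integer in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- digest::digest2int(key)
  s <- (abs(as.numeric(h)) + abs(as.numeric(seed))) %% 2147483645
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Separable Gaussian blur of a 2-D or 3-D array (reflective boundaries)
#'
#' Used to emulate partial-volume effects on the ground-truth absorption map.
#' Boundary handling is half-sample reflection, which makes the 1-D operator
#' symmetric and therefore preserves the volume mean exactly.
#'
#' @param a numeric array (2-D or 3-D)
#' @param sigma_vox standard deviation in voxels (scalar); 0 returns `a`
#' @return blurred array, same dimensions
#' @export
gaussian_blur <- function(a, sigma_vox) {
  stopifnot(sigma_vox >= 0)
  if (sigma_vox == 0) return(a)
  d <- dim(a)
  nd <- length(d)
  stopifnot(nd %in% c(2L, 3L))
  for (ax in seq_len(nd)) {
    K <- conv_matrix_reflect(d[ax], sigma_vox)
    a <- apply_along_axis(a, ax, K)
  }
  a
}

# dense n x n convolution matrix for a unit-mass Gaussian kernel with
# half-sample reflective boundary handling
conv_matrix_reflect <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in -r:r) {
      j <- i + off
      if (j < 1) j <- 1L - j
      if (j > n) j <- 2L * n + 1L - j
      K[i, j] <- K[i, j] + k[off + r + 1L]
    }
  }
  K
}

apply_along_axis <- function(a, ax, K) {
  d <- dim(a)
  perm <- c(ax, setdiff(seq_along(d), ax))
  m <- aperm(a, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = d[ax])
  m <- K %*% m
  dim(m) <- dm
  aperm(m, order(perm))
}

# k equidistant scan-slice indices spanning 1..n (both ends included)
equidistant_slices <- function(n, k = 5L) {
  unique(round(seq(1, n, length.out = k)))
}

# stable hash of a configuration object (guards train/predict drift)
config_hash <- function(x) digest::digest(x, algo = "xxhash64")
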