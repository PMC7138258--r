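# Shared fixtures, all generated in code. Heavier shared objects are cached
# in an environment so multiple test files can reuse them.

.cepaq_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cepaq_test_cache))
    assign(key, force(expr), .cepaq_test_cache)
  get(key, .cepaq_test_cache)
}

# tiny hardware setup for unit tests (12 x 10 plane)
tiny_setup <- function(nx = 12L, nz = 10L, source = source_spec("line")) {
  hardware_setup(grid_spec(c(nx, nz, 4L)), source = source)
}

# a micro preset for fast end-to-end runs (same structure as bench_preset)
micro_preset <- function() {
  p <- bench_preset("smoke")
  p$n_train <- 3L; p$n_val <- 0L; p$n_test <- 1L
  p$photons_train <- 5e3; p$photons_test <- 5e4; p$photons_phih <- 1e5
  p$fcm_min_hits <- 100; p$fcm_batch <- 1e4
  p$oxy_n_train <- 2L; p$oxy_n_test <- 1L
  p$oxy_photons_train <- 5e3; p$oxy_photons_test <- 2e4
  p$oxy_max_samples <- 2000
  p
}

# reference binning rule for the CI oracle: right-closed intervals
# (e_i, e_{i+1}], drop at/below the lower edge, overflow into the top bin
bin_oracle <- function(x, e) {
  nb <- length(e) - 1L
  if (x <= e[1]) return(0L)
  if (x > e[nb + 1L]) return(nb)
  findInterval(x, e, left.open = TRUE)
}

# naive double-loop CI encoder used as the independent oracle
ci_oracle <- function(signal, fcm, cfg) {
  counts <- matrix(0L, cfg$n_bins, cfg$n_bins)
  for (v in seq_along(fcm)) {
    f <- fcm[v]
    if (!(f > cfg$epsilon)) next
    fb <- bin_oracle(log10(f), cfg$f_edges)
    if (fb == 0L) next
    s <- signal[v]
    if (!(s > 0)) next
    sb <- bin_oracle(log10(s), cfg$s_edges)
    if (sb == 0L) next
    counts[sb, fb] <- counts[sb, fb] + 1L
  }
  counts
}
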