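test_that("NNLS solves the constrained problem", {
  A <- reference_spectra()
  # exact consistency on non-negative mixtures
  for (so2 in c(0, 0.3, 0.8, 1)) {
    x_true <- c(so2, 1 - so2) * 0.02
    b <- drop(A %*% x_true)
    fit <- nnls_fit(A, b)
    expect_equal(fit$x, x_true, tolerance = 1e-9)
  }
  # zero measurement: zero abundances, undefined saturation flagged
  u <- unmix_so2(matrix(0, 1, 3), A)
  expect_equal(unname(u$x[1, ]), c(0, 0))
  expect_true(is.na(u$so2[1]))
  expect_error(nnls_fit(cbind(A[, 1], A[, 1]), c(1, 2, 3)), "rank-deficient")
  # active-set handling when the unconstrained optimum is negative
  b_neg <- drop(A %*% c(0.05, 0)) - 0.3 * A[, 2]
  fit <- nnls_fit(A, b_neg)
  expect_gte(min(fit$x), 0)
})

test_that("NNLS matches a dense grid-search oracle to 3 decimals", {
  A <- matrix(c(2, 1, 0.5, 1, 2, 1.5), 3, 2)
  set.seed(13)
  for (i in 1:5) {
    b <- runif(3, 0, 3)
    fit <- nnls_fit(A, b)
    # two-stage grid refinement over x >= 0
    lo <- c(0, 0); hi <- c(3, 3)
    for (stage in 1:3) {
      g1 <- seq(lo[1], hi[1], length.out = 61)
      g2 <- seq(lo[2], hi[2], length.out = 61)
      gr <- as.matrix(expand.grid(g1, g2))
      sse <- colSums((A %*% t(gr) - b)^2)
      best <- gr[which.min(sse), ]
      step <- c(g1[2] - g1[1], g2[2] - g2[1])
      lo <- pmax(0, best - step); hi <- best + step
    }
    expect_lt(max(abs(fit$x - best)), 1e-3)
  }
})

test_that("MIP voxel selection", {
  S <- matrix(0, 6, 4)
  S[3, 2] <- 5
  idx <- mip_select(S, "x")
  expect_equal(idx[2], 3L + 6L * 1L)     # the only bright voxel on its line
  expect_equal(idx[1], 1L)               # all-equal line: lowest index wins
  # brute-force per-line argmax oracle
  set.seed(3)
  S2 <- matrix(runif(24), 6, 4)
  expect_equal(mip_select(S2, "x"),
               vapply(1:4, function(z) which.max(S2[, z]) + 6L * (z - 1L), 1L))
  expect_equal(mip_select(S2, "z"),
               vapply(1:6, function(x) x + 6L * (which.max(S2[x, ]) - 1L), 1L))
})

test_that("sO2 estimation modes share the evaluation voxel set", {
  A <- reference_spectra()
  so2_true <- 0.63
  # noise-free signals over a fake fluence field: dividing by the true
  # fluence then unmixing recovers the ground truth exactly
  set.seed(8)
  phi <- lapply(c(750, 800, 850), function(w) matrix(runif(30, 0.2, 1), 6, 5))
  names(phi) <- c("750", "800", "850")
  k <- 40
  mu <- lapply(names(phi), function(w)
    matrix(blood_mu_a(as.numeric(w), so2_true), 6, 5))
  names(mu) <- names(phi)
  S <- lapply(names(phi), function(w) forward_signal(mu[[w]], phi[[w]], k))
  names(S) <- names(phi)
  eval_idx <- c(3L, 11L, 28L)
  est <- estimate_so2("ce_unmix", S, eval_idx, A, scale_k = k, phi_hat = phi)
  expect_equal(est$so2, rep(so2_true, 3), tolerance = 1e-9)
  expect_identical(est$eval_idx, eval_idx)
  # raw unmixing on the same voxels sees fluence-coloured spectra instead
  raw <- estimate_so2("raw_unmix", S, eval_idx, A)
  expect_identical(raw$eval_idx, eval_idx)
  expect_error(estimate_so2("raw_unmix", S[1:2], eval_idx, A),
               "missing wavelength")
})
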