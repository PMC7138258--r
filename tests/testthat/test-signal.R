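test_that("signal formation follows the absorbed-energy model", {
  phi <- matrix(runif(40, 0.1, 1), 8, 5)
  mu <- matrix(runif(40, 0, 5), 8, 5)
  mu[1, 1] <- 0
  S <- forward_signal(mu, phi, scale_k = 10)
  expect_equal(S[1, 1], 0)
  expect_equal(unclass(forward_signal(mu, phi, 20)),
               unclass(pmin(2 * S, 255)))
  # homogeneous slice: S / phi is constant
  Sh <- forward_signal(matrix(2, 8, 5), phi, 3)
  expect_equal(unique(round(as.vector(Sh / phi), 10)), 6)
  expect_error(forward_signal(mu[1:4, ], phi, 1), "grids differ")
  # clipping flag and invertibility on unclipped voxels
  Sc <- forward_signal(mu, phi * 100, 10)
  expect_true(any(attr(Sc, "clipped")))
  mu_rec <- reconstruct_absorption(S, phi, 10)
  expect_equal(unclass(mu_rec), unclass(mu), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("noise model has the stated moments", {
  expect_equal(noise_level(2)$mult_sd, 0.10)
  expect_equal(noise_level(3)$add_mean, 1.25)
  S <- matrix(100, 500, 400)               # 2e5 voxels
  expect_identical(apply_noise(S, 0, seed = 1), S)
  S1 <- apply_noise(S, 1, seed = 4)
  n <- length(S)
  # mean: E[S'] = S + 0.125 within 4 standard errors
  se_mean <- sqrt(((100.125^2 + 0.125^2) * (1 + 0.02^2) - 100.125^2) / n)
  expect_lt(abs(mean(S1) - 100.125), 4 * se_mean)
  # variance of (S + A)(1 + M) matches the analytic value
  v_an <- (100.125^2 + 0.125^2) * (1 + 0.02^2) - 100.125^2
  expect_lt(abs(var(as.vector(S1)) / v_an - 1), 0.05)
  # additive-then-multiplicative order and reproducibility
  expect_identical(S1, apply_noise(S, 1, seed = 4))
  expect_false(identical(S1, apply_noise(S, 1, seed = 5)))
  # negative results are clipped at zero
  S0 <- apply_noise(matrix(0, 100, 100), 3, seed = 2)
  expect_gte(min(S0), 0)
})

test_that("CNR and ROI rule", {
  stats <- structure(list(avg = 4.2, std = 2.8), class = "cepaq_bg_stats")
  expect_equal(compute_cnr(9.8, stats), 2)
  expect_equal(compute_cnr(4.2, stats), 0)
  expect_equal(compute_cnr(9.8 + 2.8, stats), 3)   # CNR(S + std) = CNR(S) + 1
  expect_error(compute_cnr(1, structure(list(avg = 0, std = 0),
                                        class = "cepaq_bg_stats")), "positive")
  # brute-force oracle on a random slice; CNR exactly 2 is excluded
  # (exactly representable statistics so the boundary case is exact)
  st2 <- structure(list(avg = 4, std = 2.5), class = "cepaq_bg_stats")
  set.seed(31)
  labels <- matrix(sample(0:2, 64, TRUE), 8, 8)
  S <- matrix(runif(64, 0, 30), 8, 8)
  S[2, 2] <- 9; labels[2, 2] <- 1L            # (9 - 4) / 2.5 == 2 exactly
  mask <- roi_mask(labels, S, st2)
  oracle <- matrix(FALSE, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- labels[i, j] > 0 && (S[i, j] - 4) / 2.5 > 2
  expect_identical(mask, oracle)
  expect_false(mask[2, 2])
  expect_true(all(labels[mask] > 0))          # ROI subset of vessel labels
  expect_false(any(roi_mask(matrix(0L, 8, 8), S, st2)))
})

test_that("background statistics and scale calibration", {
  setup <- tiny_setup(16L, 12L)
  cal <- calibrate_scale_k(setup, n_photons = 5e4, seed = 3)
  expect_equal(cal$stats$avg, 4.2, tolerance = 1e-9)
  expect_gt(cal$stats$std, 0)
  # same slice twice: identical statistics
  s2 <- background_stats(setup, cal$scale_k, phi = cal$phi)
  expect_identical(cal$stats$avg, s2$avg)
  # two seeds agree within the Monte Carlo spread of the slice statistics
  s3 <- background_stats(setup, cal$scale_k, n_photons = 5e4, seed = 77)
  expect_lt(abs(s3$avg - 4.2) / 4.2, 0.05)
})
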