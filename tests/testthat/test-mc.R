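# Monte Carlo transport: analytic oracles and bookkeeping invariants.

test_that("scattering-free pencil beam follows Beer-Lambert", {
  setup <- hardware_setup(grid_spec(c(21L, 30L, 4L), 0.6),
                          source = source_spec("pencil", position = 6.3))
  h <- 0.6
  mu_a <- matrix(1, 21, 30)          # cm^-1
  mu_s <- matrix(0, 21, 30)
  fl <- simulate_fluence(mu_a, mu_s, setup, 1e5, seed = 12)
  a <- 0.1                            # mm^-1
  z1 <- (seq_len(30) - 1) * h; z2 <- z1 + h
  el <- (exp(-a * z1) - exp(-a * z2)) / a
  int_u2 <- 2 / a^3 - exp(-a * h) * (h^2 / a + 2 * h / a^2 + 2 / a^3)
  el2 <- a * exp(-a * z1) * int_u2 + h^2 * exp(-a * z2)
  se <- sqrt((el2 - el^2) / 1e5) / h^2
  prof <- fl$phi[11, ]               # beam column (pencil at voxel center)
  expect_true(all(abs(prof - el / h^2) <= 3 * se))
})

test_that("energy ledger balances exactly", {
  setup <- tiny_setup()
  mu_a <- matrix(runif(120, 0.05, 3), 12, 10)
  mu_s <- matrix(1.5, 12, 10)
  fl <- simulate_fluence(mu_a, mu_s, setup, 2e4, seed = 5,
                         estimator = "deposition")
  led <- fl$ledger
  expect_lt(abs(led[["launched"]] + led[["roulette_gain"]] -
                led[["deposited"]] - led[["exited"]] -
                led[["roulette_lost"]]), 1e-9 * led[["launched"]])
  expect_lte(led[["deposited"]], led[["launched"]] + led[["roulette_gain"]])
  expect_true(all(fl$phi >= 0) && all(is.finite(fl$phi)))
})

test_that("deposition and track-length estimators agree; mu_a = 0 handled", {
  setup <- tiny_setup()
  mu_a <- matrix(0.5, 12, 10); mu_a[3, ] <- 0    # a zero-absorption stripe
  mu_s <- matrix(1.5, 12, 10)
  ft <- simulate_fluence(mu_a, mu_s, setup, 2e5, seed = 2)
  fd <- simulate_fluence(mu_a, mu_s, setup, 2e5, seed = 2,
                         estimator = "deposition")
  # same photons: deposition matches track-length within MC correlation
  expect_lt(median(abs(fd$phi - ft$phi) / ft$phi), 0.1)
  # mu_a = 0 voxels fall back to the (finite) track value
  expect_true(all(is.finite(fd$phi[3, ])))
  expect_identical(fd$phi[3, ], ft$phi[3, ])
  expect_error(simulate_fluence(matrix(0, 4, 4), matrix(0, 4, 4),
                                hardware_setup(grid_spec(c(4L, 4L, 2L))),
                                100, 1, estimator = "deposition"),
               "all-zero attenuation")
})

test_that("homogeneous fluence: symmetry, depth decay, convergence", {
  setup <- tiny_setup(16L, 12L)
  fh <- homogeneous_fluence(setup, 2e5, seed = 8)
  # identical contract to simulate_fluence on a uniform slice
  fl <- simulate_fluence(matrix(0.1, 16, 12), matrix(1.5, 16, 12), setup,
                         2e5, seed = 8)
  expect_identical(fh$phi, fl$phi)
  # left/right mirror symmetry of a centered source within 3 SE
  dphi <- abs(fh$phi - fh$phi[16:1, ])
  dse <- 3 * sqrt(fh$se^2 + fh$se[16:1, ]^2)
  expect_gt(mean(dphi <= pmax(dse, 1e-12)), 0.98)
  # central-axis depth decay beyond the first voxel (3 SE slack)
  centre <- (fh$phi[8, ] + fh$phi[9, ]) / 2
  cse <- sqrt(fh$se[8, ]^2 + fh$se[9, ]^2) / 2
  drops <- diff(centre[-1])
  slack <- 3 * sqrt(cse[-c(1, 2)]^2 + cse[2:(length(cse) - 1)]^2)
  expect_true(all(drops <= slack))
  # doubling the photon count shrinks the SE by about sqrt(2)
  f2 <- homogeneous_fluence(setup, 4e5, seed = 9)
  ratio <- median(fh$se / f2$se)
  expect_gt(ratio, 1.2); expect_lt(ratio, 1.7)
})

test_that("single-target FCM satisfies its contract", {
  setup <- tiny_setup(10L, 8L)
  fcm <- simulate_fcm(c(5L, 4L), setup, min_target_hits = 500, seed = 3,
                      batch_photons = 5e3, max_batches = 200)
  expect_gte(fcm$hits, 500)
  expect_equal(fcm$fcm[5, 4], 1)
  expect_true(all(fcm$fcm >= 0 & fcm$fcm <= 1))
  # the illuminated column above the target contributes strongly
  expect_gt(min(fcm$fcm[5, 1:4]), 0.2)
  # unreachable quota errors and reports the achieved count
  expect_error(simulate_fcm(c(5L, 4L), setup, min_target_hits = 1e7,
                            seed = 3, batch_photons = 1e3, max_batches = 2),
               "achieved")
})

test_that("ballistic FCM is concentrated on the beam column", {
  setup <- hardware_setup(grid_spec(c(9L, 8L, 2L)),
                          source = source_spec("pencil", position = 2.7),
                          bg_mu_a = 0.1, bg_mu_s_prime = 0)
  fcm <- simulate_fcm(c(5L, 6L), setup, min_target_hits = 200, seed = 1,
                      batch_photons = 5e3, max_batches = 100)
  expect_true(all(fcm$fcm[5, 1:6] > 0.999))   # on-axis voxels above target
  expect_lt(max(fcm$fcm[-5, ]), 1e-6)         # everything off-axis
})

test_that("FCM bank matches the single-target estimator and is reproducible", {
  setup <- tiny_setup(4L, 4L)
  bank <- precompute_fcm_bank(setup, min_target_hits = 300, seed = 6,
                              batch_photons = 2e3, max_batches = 200)
  expect_identical(dim(bank$bank), c(16L, 16L))
  expect_equal(unname(diag(bank$bank)), rep(1, 16))
  expect_true(all(bank$bank >= 0 & bank$bank <= 1))
  expect_true(all(bank$hits >= 300))
  # statistically consistent with the per-target route (independent seeds)
  single <- simulate_fcm(11L, setup, min_target_hits = 4000, seed = 99,
                         batch_photons = 5e3, max_batches = 400)
  expect_lt(max(abs(bank$bank[, 11] - as.vector(single$fcm))), 0.1)
  # determinism
  bank2 <- precompute_fcm_bank(setup, min_target_hits = 300, seed = 6,
                               batch_photons = 2e3, max_batches = 200)
  expect_identical(bank$bank, bank2$bank)
})

test_that("cached banks refuse a mismatched hardware setup", {
  setup <- tiny_setup(4L, 4L)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  precompute_fcm_bank(setup, 50, seed = 1, batch_photons = 1e3,
                      max_batches = 100, cache_file = f)
  other <- hardware_setup(grid_spec(c(4L, 4L, 4L)), bg_mu_a = 0.2)
  expect_error(load_fcm_bank(f, other), "hash mismatch")
  expect_silent(load_fcm_bank(f, setup))
})
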