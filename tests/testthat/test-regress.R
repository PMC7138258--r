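micro_ctx <- function() cached("micro_ctx", prepare_context(micro_preset(), seed = 5))

test_that("sample plan arithmetic", {
  grid <- grid_spec(c(16L, 12L, 8L), 0.6)
  ds <- build_dataset(dataset_spec("DSbase", 4, 2, 1), seed = 2, grid = grid)
  plan <- plan_training_samples(ds, "train")
  expect_equal(nrow(plan), 4 * 5 * 16 * 12)
  expect_equal(length(unique(plan$slice)), 5L)
  expect_equal(nrow(plan_training_samples(ds, "test")), 1 * 5 * 16 * 12)
  e <- plan_training_samples(build_dataset(dataset_spec("DSbase", 0, 0, 0), 1, grid))
  expect_equal(nrow(e), 0L)
})

test_that("training sets balance ROI and background 1:1, reproducibly", {
  ctx <- micro_ctx()
  p <- ctx$preset
  ds <- build_dataset(dataset_spec("DSbase", 2, 0, 0), seed = 21,
                      grid = ctx$setup$grid)
  ts <- make_training_set(ds, ctx$setup, ctx$bank, ctx$phi_h, ctx$config,
                          ctx$scale_k, ctx$stats, p$photons_train, seed = 3)
  expect_equal(sum(ts$roi), sum(!ts$roi))
  expect_equal(sum(ts$roi), ts$n_roi)        # no ROI sample is ever dropped
  expect_true(all(ts$labels > 0))
  ts2 <- make_training_set(ds, ctx$setup, ctx$bank, ctx$phi_h, ctx$config,
                           ctx$scale_k, ctx$stats, p$photons_train, seed = 3)
  expect_identical(ts$features, ts2$features)
  expect_identical(ts$provenance, ts2$provenance)
})

test_that("homogeneous volumes give unit fluence-correction labels", {
  ctx <- micro_ctx()
  # a zero-vessel item: phi = phi_h up to Monte Carlo noise, so labels ~ 1;
  # balancing is impossible (no ROI) and must error
  ds <- build_dataset(dataset_spec("DSvessel", 1, 0, 0), seed = 4,
                      grid = ctx$setup$grid)
  ds$train[[1]]$n_vessels <- 0L
  ds$train[[1]]$vessels <- ds$train[[1]]$vessels[0, ]
  expect_error(make_training_set(ds, ctx$setup, ctx$bank, ctx$phi_h,
                                 ctx$config, ctx$scale_k, ctx$stats,
                                 ctx$preset$photons_train, seed = 1),
               "balancing impossible")
  ts <- make_training_set(ds, ctx$setup, ctx$bank, ctx$phi_h, ctx$config,
                          ctx$scale_k, ctx$stats, ctx$preset$photons_train,
                          seed = 1, balance = FALSE)
  expect_lt(abs(median(ts$labels) - 1), 0.05)
})

test_that("fluence prediction contracts", {
  ctx <- micro_ctx()
  # a model trained on constant labels 1 predicts phi_hat = phi_h exactly
  set.seed(2)
  X <- matrix(rpois(300 * 20, 2), 300, 20)
  ts <- structure(list(features = X, labels = rep(1, 300),
                       config_hash = ctx$config$hash,
                       label_type = "fluence_correction"),
                  class = "cepaq_training_set")
  model <- train_regressor(ts, n_trees = 10, seed = 1)
  ph <- runif(7, 0.1, 2)
  feats <- X[1:7, ]
  attr(feats, "config_hash") <- ctx$config$hash
  expect_equal(predict_fluence(model, feats, ph), ph)
  # hull property: phi_hat bounded by label range x phi_h range
  expect_true(all(predict_fluence(model, feats, ph) > 0))
  # configuration-hash drift is refused
  attr(feats, "config_hash") <- "deadbeef"
  expect_error(predict_fluence(model, feats, ph), "hash mismatch")
})

test_that("absorption reconstruction inverts the signal model", {
  phi <- matrix(runif(24, 0.2, 1), 6, 4)
  mu <- matrix(runif(24, 0.05, 4), 6, 4)
  S <- forward_signal(mu, phi, 12)
  expect_equal(unclass(reconstruct_absorption(S, phi, 12)), unclass(mu),
               ignore_attr = TRUE, tolerance = 1e-12)
  # joint rescaling of S and k leaves mu_a unchanged
  expect_equal(unclass(reconstruct_absorption(S * 3, phi, 36)), unclass(mu),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(reconstruct_absorption(S, phi - 1, 12), "non-positive")
  # static homogeneous correction underestimates absorption in a vessel:
  # inside an absorber phi < phi_h, so S / (k phi_h) < S / (k phi) = mu_a
  phi_h <- phi * 2
  mu_static <- reconstruct_absorption(S, phi_h, 12)
  expect_true(all(mu_static < mu))
})
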