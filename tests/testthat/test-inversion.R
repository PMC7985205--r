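test_that("target normalization maps range ends to 0/1 and inverts exactly", {
  fit <- data.frame(n = c(1.3, 1.6, 1.45), mu_s_prime = c(0.05, 50, 2),
                    mu_a = c(0.01, 10, 0.3))
  sc <- fit_target_scaler(fit)
  z <- normalize_targets(fit, sc)
  expect_equal(unname(z[1:2, "n"]), c(0, 1))
  expect_equal(unname(z[3, "n"]), 0.5)
  expect_true(all(z >= 0 & z <= 1))
  # log10 transform for the coefficients: geometric midpoints map to 0.5
  mid <- data.frame(n = 1.3, mu_s_prime = sqrt(0.05 * 50),
                    mu_a = sqrt(0.01 * 10))
  expect_equal(unname(normalize_targets(mid, sc)[, 2:3]), c(0.5, 0.5),
               tolerance = 1e-12)
  back <- denormalize_targets(z, sc)
  expect_equal(unname(back[, "n"]), fit$n, tolerance = 1e-12)
  expect_equal(unname(back[, "mu_s_prime"]), fit$mu_s_prime,
               tolerance = 1e-12)
  expect_equal(unname(back[, "mu_a"]), fit$mu_a, tolerance = 1e-12)
  expect_error(fit_target_scaler(data.frame(n = c(1.4, 1.4),
                                            mu_s_prime = c(1, 2),
                                            mu_a = c(0.1, 1))),
               "degenerate")
})

test_that("a memorizable micro-set is driven to near-zero training loss", {
  ds <- make_micro_dataset(n_runs = 50, n_photons = 400, seed = 19)
  model <- train_inverse_model(ds, hidden_size = 150, epochs = 5000,
                               seed = 4)
  expect_lt(tail(model$training$loss_history, 1), 1e-3)
  # memorization oracle: training records recovered within ~1%
  pred <- predict(model, ds$records)
  rel_n <- abs(pred$n - ds$records$n) / ds$records$n
  expect_lt(stats::median(rel_n), 0.01)
  expect_equal(model$layer_sizes, c(21, 150, 150, 150, 3))
})

test_that("training is deterministic for a fixed seed", {
  ds <- make_micro_dataset(n_runs = 15, n_photons = 150, seed = 23)
  m1 <- train_inverse_model(ds, hidden_size = 20, epochs = 30, seed = 5)
  m2 <- train_inverse_model(ds, hidden_size = 20, epochs = 30, seed = 5)
  expect_identical(m1$training$loss_history, m2$training$loss_history)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_inverse_model(ds, hidden_size = 20, epochs = 30, seed = 6)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("batch prediction equals record-by-record prediction", {
  ds <- make_micro_dataset(n_runs = 12, n_photons = 150, seed = 29)
  model <- train_inverse_model(ds, hidden_size = 25, epochs = 50, seed = 1)
  batch <- predict(model, ds$records)
  X <- as.matrix(ds$records[, model$feature_labels])
  for (i in seq_len(nrow(X))) {
    single <- predict(model, X[i, , drop = FALSE])
    expect_identical(as.numeric(single), as.numeric(batch[i, ]))
  }
})

test_that("predicted coefficients are strictly positive by construction", {
  ds <- make_micro_dataset(n_runs = 12, n_photons = 150, seed = 31)
  model <- train_inverse_model(ds, hidden_size = 10, epochs = 5, seed = 1)
  pred <- predict(model, ds$records)  # nearly untrained network
  expect_true(all(pred$mu_s_prime > 0))
  expect_true(all(pred$mu_a > 0))
})

test_that("model files round-trip to bit-identical predictions", {
  ds <- make_micro_dataset(n_runs = 15, n_photons = 150, seed = 37)
  model <- train_inverse_model(ds, hidden_size = 30, epochs = 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_inverse_model(model, path)
  back <- load_inverse_model(path)
  expect_identical(predict(back, ds$records), predict(model, ds$records))
  expect_equal(back$layer_sizes, model$layer_sizes)
  expect_error(load_inverse_model(
    withr::local_tempfile(lines = "{\"format\": \"other\"}",
                          fileext = ".json")), "inverse-model")
})

test_that("invalid features are rejected, never silently extrapolated", {
  ds <- make_micro_dataset(n_runs = 12, n_photons = 150, seed = 41)
  model <- train_inverse_model(ds, hidden_size = 10, epochs = 5, seed = 1)
  empty <- compute_moments(data.frame(side = character(), r = numeric(),
                                      weight = numeric(), time = numeric()))
  expect_error(predict(model, empty), "invalid|empty")
  bad <- as.matrix(ds$records[1, model$feature_labels])
  bad[1, 3] <- NaN
  expect_error(predict(model, bad), "finite")
})
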