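test_that("moment indices enumerate canonically and count (K+1)(K+2)/2", {
  idx5 <- moment_indices(5)
  expect_identical(nrow(idx5), 21L)
  expect_identical(nrow(moment_indices(2)), 6L)
  expect_identical(moment_indices(0)$label, "W")
  # canonical order: total order ascending, alpha descending within order
  expect_true(all(diff(idx5$alpha + idx5$beta) >= 0))
  expect_identical(idx5$label[1:6],
                   c("W", "r_mean", "t_mean", "m_2_0", "m_1_1", "m_0_2"))
  ord2 <- idx5[idx5$alpha + idx5$beta == 4L, ]
  expect_identical(ord2$alpha, 4:0)
  expect_error(moment_indices(-1), "non-negative")
})

test_that("point masses and simple configurations evaluate exactly", {
  one <- data.frame(side = "reflection", r = 2, weight = 0.7, time = 50)
  fv <- compute_moments(one)
  expect_equal(unname(fv[["W"]]), 0.7)
  expect_equal(unname(fv[["r_mean"]]), 2)
  expect_equal(unname(fv[["t_mean"]]), 50)
  expect_true(all(abs(fv[4:21]) < 1e-12))

  two <- data.frame(side = "reflection", r = c(0, 2), weight = c(1, 1),
                    time = c(10, 10))
  fv2 <- compute_moments(two, max_order = 2)
  expect_equal(unname(fv2[c("W", "r_mean", "t_mean",
                            "m_2_0", "m_1_1", "m_0_2")]),
               c(2, 1, 10, 1, 0, 0))
})

test_that("moments agree with the brute-force oracle", {
  for (seed in c(42, 43, 44)) {
    rec <- make_exit_log(n = 9, seed = seed)
    fv <- compute_moments(rec)
    oracle <- brute_force_moments(rec)
    idx <- attr(fv, "indices")
    for (k in seq_len(nrow(idx))) {
      key <- sprintf("m_%d_%d", idx$alpha[k], idx$beta[k])
      expect_equal(unname(fv[[k]]), unname(oracle[[key]]),
                   tolerance = 1e-12, label = key)
    }
  }
})

test_that("weight scaling touches only W; time shifts touch only t_mean", {
  rec <- make_exit_log(n = 10, seed = 5)
  fv <- compute_moments(rec)

  rec_k <- rec
  rec_k$weight <- rec$weight * 3.7
  fv_k <- compute_moments(rec_k)
  expect_equal(unname(fv_k[["W"]]), unname(3.7 * fv[["W"]]))
  expect_equal(as.numeric(fv_k[-1]), as.numeric(fv[-1]), tolerance = 1e-12)

  rec_t <- rec
  rec_t$time <- rec$time + 250
  fv_t <- compute_moments(rec_t)
  expect_equal(unname(fv_t[["t_mean"]]), unname(fv[["t_mean"]]) + 250,
               tolerance = 1e-12)
  keep <- setdiff(names(fv), "t_mean")
  expect_equal(as.numeric(fv_t[keep]), as.numeric(fv[keep]),
               tolerance = 1e-9)
})

test_that("even pure central moments are non-negative", {
  res <- run_simulation(baseline_properties(), slab_geometry(),
                        sim_config(2000, seed = 21))
  fv <- compute_moments(res)
  for (lab in c("m_2_0", "m_0_2", "m_4_0", "m_0_4"))
    expect_gte(unname(fv[[lab]]), 0)
  expect_gt(unname(fv[["W"]]), 0)
})

test_that("summation order is pinned: permuting records changes nothing", {
  rec <- make_exit_log(n = 50, seed = 9)
  fv <- compute_moments(rec)
  set.seed(1)
  fv_perm <- compute_moments(rec[sample(nrow(rec)), ])
  expect_identical(as.numeric(fv), as.numeric(fv_perm))
})

test_that("an empty detector is flagged invalid, never silent zeros", {
  empty <- data.frame(side = character(), r = numeric(),
                      weight = numeric(), time = numeric())
  fv <- compute_moments(empty)
  expect_false(attr(fv, "valid"))
  expect_true(all(is.na(fv)))
  # transmission-only log is empty on the reflection side
  tr <- data.frame(side = "transmission", r = 1, weight = 1, time = 5)
  expect_false(attr(compute_moments(tr), "valid"))
  expect_true(attr(compute_moments(tr, side = "transmission"), "valid"))
})

test_that("specular record is included by default and switchable", {
  res <- run_simulation(baseline_properties(), slab_geometry(),
                        sim_config(2000, seed = 22))
  with_sp <- compute_moments(res)
  without_sp <- compute_moments(res, include_specular = FALSE)
  expect_equal(unname(with_sp[["W"]] - without_sp[["W"]]),
               res$specular_record$weight, tolerance = 1e-9)
  expect_lt(unname(with_sp[["t_mean"]]), unname(without_sp[["t_mean"]]))
})
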