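test_that("free-path sampling inverts the exponential CDF", {
  expect_equal(sample_free_path(2, 0.5), log(2) / 2, tolerance = 1e-12)
  expect_equal(sample_free_path(1, exp(-1)), 1, tolerance = 1e-12)
  expect_lt(sample_free_path(5, 1 - 1e-12), 1e-9)
  expect_error(sample_free_path(-1, 0.5), "positive")
  expect_error(sample_free_path(2, 0), "inside")
})

test_that("Henyey-Greenstein sampling matches the closed-form inverse CDF", {
  expect_equal(sample_scatter_cosine(0.85, 0), -1)
  expect_equal(sample_scatter_cosine(0.85, 1), 1)
  expect_equal(sample_scatter_cosine(0.85, 0.5), 0.9679375, tolerance = 1e-7)
  expect_equal(sample_scatter_cosine(0, c(0, 0.5, 1)), c(-1, 0, 1))
  expect_error(sample_scatter_cosine(1, 0.5), "\\|g\\| < 1")
})

test_that("sampling oracles: empirical means and HG goodness of fit", {
  set.seed(101)
  u <- runif(1e6)
  d <- sample_free_path(2, u)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.5), 4 * se)

  ct <- sample_scatter_cosine(0.85, u)
  se_ct <- sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - 0.85), 4 * se_ct)
  expect_true(all(ct >= -1 & ct <= 1))

  # binned chi-square against the analytic HG CDF at alpha = 0.01
  breaks <- c(-1, seq(0, 1, length.out = 21))
  observed <- table(cut(ct, breaks, include.lowest = TRUE))
  p <- diff(hg_cdf(breaks, 0.85))
  expect_gt(suppressWarnings(
    chisq.test(as.numeric(observed), p = p / sum(p))$p.value), 0.01)
})

test_that("direction deflection preserves unit norm and the polar cosine", {
  expect_equal(new_direction(c(0, 0, 1), 1, 2.3), c(0, 0, 1))
  expect_equal(new_direction(c(0, 0, 1), 0, 0), c(1, 0, 0))
  set.seed(7)
  for (i in 1:200) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    ct <- runif(1, -1, 1)
    phi <- runif(1, 0, 2 * pi)
    out <- new_direction(v, ct, phi)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    expect_equal(sum(out * v), ct, tolerance = 1e-10)
  }
  # near-axial special case keeps the contract too
  out <- new_direction(c(1e-11, 0, 1), 0.3, 1.1)
  expect_equal(sum(out * c(0, 0, 1)), 0.3, tolerance = 1e-10)
  expect_error(new_direction(c(0, 0, 2), 0.5, 0), "unit")
})

test_that("Beer-Lambert attenuation follows exp(-mu_a d)", {
  expect_equal(attenuate_weight(1, 0, 123), 1)
  expect_equal(attenuate_weight(1, 0.1, 1), exp(-0.1))
  expect_equal(attenuate_weight(0.5, 10, 1), 0.5 * exp(-10))
  expect_error(attenuate_weight(-1, 0.1, 1), ">")
})

test_that("Fresnel reflectance: normal incidence, TIR, matched boundary", {
  expect_equal(fresnel_reflectance(1, 1.4, 1), (0.4 / 2.4)^2,
               tolerance = 1e-12)
  expect_identical(fresnel_reflectance(1.4, 1, 0.5), 1)  # beyond critical
  expect_identical(fresnel_reflectance(1.33, 1.33, 0.7), 0)
  # reflectance grows towards grazing incidence
  r <- fresnel_reflectance(1, 1.4, c(1, 0.8, 0.5, 0.2, 0.05))
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("Russian roulette passes high weights and is unbiased below", {
  expect_identical(russian_roulette(0.5, 1e-6, 10, 0.99), 0.5)
  expect_equal(russian_roulette(1e-7, 1e-6, 10, 0.05), 1e-6)
  expect_identical(russian_roulette(1e-7, 1e-6, 10, 0.5), 0)
  set.seed(3)
  out <- vapply(runif(2e4), function(u) russian_roulette(1e-7, 1e-6, 10, u),
                numeric(1))
  expect_equal(mean(out), 1e-7, tolerance = 0.05)
})

test_that("energy is conserved without roulette", {
  p <- optical_properties(n = 1, g = 0.85, mu_s = 1 / 0.15, mu_a = 0)
  res <- run_simulation(p, slab_geometry(),
                        sim_config(2e4, roulette_threshold = 0, seed = 5))
  total <- sum(res$exit_records$weight) + res$lost_weight
  expect_equal(total, res$launch_weight, tolerance = 1e-9)
  expect_equal(res$absorbed_weight, 0, tolerance = 1e-9)

  # with absorption, the full ledger still balances
  p2 <- baseline_properties()
  res2 <- run_simulation(p2, slab_geometry(),
                         sim_config(5e3, roulette_threshold = 0, seed = 5))
  total2 <- res2$specular_record$weight + sum(res2$exit_records$weight) +
    res2$absorbed_weight + res2$lost_weight
  expect_equal(total2, 5e3, tolerance = 1e-9)
})

test_that("identical seeds reproduce bit-identical runs", {
  p <- baseline_properties()
  cfg <- sim_config(2000, seed = 99)
  r1 <- run_simulation(p, slab_geometry(), cfg)
  r2 <- run_simulation(p, slab_geometry(), cfg)
  expect_identical(r1$exit_records, r2$exit_records)
  expect_identical(r1$absorbed_weight, r2$absorbed_weight)
  r3 <- run_simulation(p, slab_geometry(), sim_config(2000, seed = 100))
  expect_false(identical(r1$exit_records, r3$exit_records))
})

test_that("specular deduction appears as a weight-(1/36) record at r=0, t=0", {
  p <- baseline_properties()
  res <- run_simulation(p, slab_geometry(), sim_config(1000, seed = 2))
  expect_equal(res$specular_record$weight, 1000 * (0.4 / 2.4)^2,
               tolerance = 1e-12)
  expect_identical(res$specular_record$r, 0)
  expect_identical(res$specular_record$time, 0)
  expect_equal(res$launch_weight, 1000 * (1 - (0.4 / 2.4)^2),
               tolerance = 1e-12)
  # matched entry face: no specular record
  pm <- optical_properties(1, 0.85, 1 / 0.15, 0.1)
  expect_null(run_simulation(pm, slab_geometry(),
                             sim_config(100, seed = 2))$specular_record)
})

test_that("ballistic limit: weak scattering transmits exp(-mu_s L) at L n/c", {
  p <- optical_properties(n = 1.5, g = 0.85, mu_s = 1e-3, mu_a = 0)
  geom <- slab_geometry(thickness = 10, n_ambient_top = 1.5,
                        n_ambient_bottom = 1.5)
  res <- run_simulation(p, geom, sim_config(2e4, seed = 8))
  trans <- res$exit_records[res$exit_records$side == "transmission", ]
  ballistic <- trans[trans$r < 1e-9, ]
  expect_equal(sum(ballistic$weight) / 2e4, exp(-0.01), tolerance = 0.01)
  # arrival at the phase velocity: 10 mm at n = 1.5 -> 50.0346 ps
  expect_equal(unique(round(ballistic$time, 6)),
               round(10 * 1.5 / 0.299792458, 6))
})

test_that("reflectance responds monotonically to absorption (common seeds)", {
  g <- slab_geometry()
  refl_weight <- function(mu_a) {
    p <- optical_properties(1.4, 0.85, 1 / 0.15, mu_a)
    res <- run_simulation(p, g, sim_config(5e3, seed = 31))
    sum(res$exit_records$weight[res$exit_records$side == "reflection"])
  }
  w <- vapply(c(0.05, 0.1, 0.2, 0.4), refl_weight, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("single-photon propagation reproduces the batched run", {
  p <- baseline_properties()
  cfg <- sim_config(20, seed = 77)
  full <- run_simulation(p, slab_geometry(), cfg)
  singles <- lapply(0:19, function(i)
    propagate_photon(p, slab_geometry(), cfg, photon_index = i))
  rec <- do.call(rbind, lapply(singles, `[[`, "exit_records"))
  rownames(rec) <- NULL
  expect_equal(rec, full$exit_records)
  expect_equal(sum(vapply(singles, `[[`, numeric(1), "absorbed_weight")),
               full$absorbed_weight, tolerance = 1e-12)
})

test_that("histogram export covers the reflected weight", {
  res <- run_simulation(baseline_properties(), slab_geometry(),
                        sim_config(5e3, seed = 13))
  h <- reflectance_histograms(res)
  refl <- sum(res$exit_records$weight[res$exit_records$side == "reflection"]) +
    res$specular_record$weight
  expect_equal(sum(h$temporal$weight) * 5e3, refl, tolerance = 1e-9)
  expect_equal(sum(h$radial$weight) * 5e3, refl, tolerance = 1e-9)
})
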