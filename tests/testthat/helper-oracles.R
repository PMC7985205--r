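# Independent brute-force oracles used to freeze expected values.

# Direct nested-loop evaluation of the weighted central cross-moments of an
# exit log, independent of the vectorized implementation.
brute_force_moments <- function(rec, max_order = 5L) {
  idx <- expand.grid(alpha = 0:max_order, beta = 0:max_order)
  idx <- idx[idx$alpha + idx$beta <= max_order, ]
  W <- 0
  for (i in seq_len(nrow(rec))) W <- W + rec$weight[i]
  r_mean <- 0
  t_mean <- 0
  for (i in seq_len(nrow(rec))) {
    r_mean <- r_mean + rec$weight[i] * rec$r[i] / W
    t_mean <- t_mean + rec$weight[i] * rec$time[i] / W
  }
  get_moment <- function(a, b) {
    if (a + b == 0) return(W)
    if (a == 1 && b == 0) return(r_mean)
    if (a == 0 && b == 1) return(t_mean)
    s <- 0
    for (i in seq_len(nrow(rec)))
      s <- s + rec$weight[i] * (rec$r[i] - r_mean)^a * (rec$time[i] - t_mean)^b
    s / W
  }
  out <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) out[k] <- get_moment(idx$alpha[k], idx$beta[k])
  names(out) <- sprintf("m_%d_%d", idx$alpha, idx$beta)
  out
}

# Closed-form CDF of the Henyey-Greenstein scattering cosine, for binned
# goodness-of-fit checks.
hg_cdf <- function(c, g) {
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
}

# A small exit log with irregular weights/positions/times, reproducible.
make_exit_log <- function(n = 8, seed = 42) {
  set.seed(seed)
  data.frame(
    side = "reflection",
    r = round(runif(n, 0, 5), 3),
    weight = round(runif(n, 0.1, 1), 3),
    time = round(runif(n, 1, 200), 2))
}

baseline_properties <- function() optical_properties(1.4, 0.85, 1 / 0.15, 0.1)

# Tiny end-to-end dataset: cheap enough for unit tests, rich enough to train.
make_micro_dataset <- function(n_runs = 40, n_photons = 500, seed = 11,
                               n_test = 0) {
  ds <- generate_dataset(
    n_runs, parameter_ranges(), slab_geometry(),
    sim_config(n_photons = n_photons), master_seed = seed)
  if (n_test > 0) ds <- split_dataset(ds, n_test, seed = seed + 1)
  ds
}
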