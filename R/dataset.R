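#' Biological parameter ranges
#'
#' Bounds of the optical-property space sampled when building training data,
#' chosen to span values measured for biological tissues: refractive index
#' 1.3-1.6, anisotropy 0.5-0.95, scattering coefficient 0.1-100 mm^-1 and
#' absorption coefficient 0.01-10 mm^-1. The index and anisotropy are drawn
#' linear-uniform; the two coefficients span several decades and are drawn
#' log-uniform.
#'
#' @param n_min,n_max Refractive-index bounds.
#' @param g_min,g_max Anisotropy bounds.
#' @param mu_s_min,mu_s_max Scattering-coefficient bounds (mm^-1).
#' @param mu_a_min,mu_a_max Absorption-coefficient bounds (mm^-1).
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(n_min = 1.3, n_max = 1.6,
                             g_min = 0.5, g_max = 0.95,
                             mu_s_min = 0.1, mu_s_max = 100,
                             mu_a_min = 0.01, mu_a_max = 10) {
  stopifnot(n_min < n_max, g_min < g_max,
            mu_s_min < mu_s_max, mu_a_min < mu_a_max,
            n_min >= 1, abs(g_min) < 1, abs(g_max) < 1,
            mu_s_min > 0, mu_a_min > 0)
  structure(
    list(n_min = n_min, n_max = n_max, g_min = g_min, g_max = g_max,
         mu_s_min = mu_s_min, mu_s_max = mu_s_max,
         mu_a_min = mu_a_min, mu_a_max = mu_a_max),
    class = "parameter_ranges")
}

#' Draw one optical-property realization
#'
#' Maps four independent uniform deviates to one point of the parameter
#' space: `n` and `g` by linear interpolation between their bounds, `mu_s`
#' and `mu_a` by interpolation in log space (log-uniform marginals), so the
#' decades-wide coefficient ranges are sampled evenly.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param u Numeric vector of four uniform deviates in `[0, 1]`, in the
#'   order (n, g, mu_s, mu_a).
#' @return An [optical_properties()] object inside the ranges.
#' @examples
#' sample_parameters(parameter_ranges(), c(0.5, 0.5, 0.5, 0.5))
#' @export
sample_parameters <- function(ranges, u) {
  stopifnot(inherits(ranges, "parameter_ranges"),
            is.numeric(u), length(u) == 4L)
  if (any(u < 0 | u > 1)) stop("deviates `u` must lie in [0, 1]")
  optical_properties(
    n = ranges$n_min + (ranges$n_max - ranges$n_min) * u[1],
    g = ranges$g_min + (ranges$g_max - ranges$g_min) * u[2],
    mu_s = 10^(log10(ranges$mu_s_min) +
                 (log10(ranges$mu_s_max) - log10(ranges$mu_s_min)) * u[3]),
    mu_a = 10^(log10(ranges$mu_a_min) +
                 (log10(ranges$mu_a_max) - log10(ranges$mu_a_min)) * u[4]))
}

#' Generate a labeled moment dataset
#'
#' Builds the training corpus for the inverse problem: for each run, draws
#' an optical-property realization from `ranges`, simulates photon transport
#' through `geometry` with a run-specific seed derived from `master_seed`,
#' and compresses the reflected exit log into the canonical moment features.
#' Runs whose reflection detector records no weight (possible at extreme
#' absorption) are dropped and counted, never imputed.
#'
#' @param n_runs Number of Monte Carlo runs to generate (>= 1).
#' @param ranges A [parameter_ranges()] object.
#' @param geometry A [slab_geometry()] object.
#' @param sim_config A [sim_config()] template; its `seed` is ignored and
#'   replaced per run.
#' @param master_seed Integer seed governing both the parameter draws and
#'   every per-run simulation substream; regeneration with the same value is
#'   bit-identical.
#' @param max_order Highest moment order for featurization (default 5).
#' @param include_specular Passed to [compute_moments()].
#' @return An object of class `moment_dataset`: a list with `records` (data
#'   frame with `run_id`, `seed`, truth columns `n`, `g`, `mu_s`, `mu_a`,
#'   `mu_s_prime` and the 21 feature columns in canonical order), `ranges`,
#'   `geometry`, `sim_config`, `n_dropped`, `max_order` and (once
#'   [split_dataset()] has run) a `split` factor.
#' @export
generate_dataset <- function(n_runs, ranges = parameter_ranges(),
                             geometry = slab_geometry(),
                             sim_config = tissueoptics::sim_config(n_photons = 2.5e5),
                             master_seed = 1, max_order = 5L,
                             include_specular = TRUE) {
  stopifnot(n_runs >= 1)
  labels <- feature_labels(max_order)
  run_seeds <- derive_seeds(master_seed, n_runs)
  u_mat <- matrix(derive_uniforms(master_seed, 4L * n_runs), ncol = 4L,
                  byrow = TRUE)

  rows <- vector("list", n_runs)
  n_dropped <- 0L
  for (i in seq_len(n_runs)) {
    props <- sample_parameters(ranges, u_mat[i, ])
    cfg <- sim_config
    cfg$seed <- run_seeds[i]
    res <- suppressWarnings(run_simulation(props, geometry, cfg))
    fv <- compute_moments(res, max_order = max_order,
                          include_specular = include_specular)
    if (!attr(fv, "valid")) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[i]] <- c(run_id = i, seed = run_seeds[i],
                   n = props$n, g = props$g, mu_s = props$mu_s,
                   mu_a = props$mu_a, mu_s_prime = props$mu_s_prime,
                   stats::setNames(as.numeric(fv), labels))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("every generated run had an empty reflection detector")
  records <- as.data.frame(do.call(rbind, rows))
  if (n_dropped > 0L)
    message(sprintf("dropped %d run(s) with empty reflection detectors",
                    n_dropped))
  structure(
    list(records = records, ranges = ranges, geometry = geometry,
         sim_config = sim_config, master_seed = master_seed,
         max_order = as.integer(max_order), n_dropped = n_dropped,
         split = NULL),
    class = "moment_dataset")
}

#' @export
print.moment_dataset <- function(x, ...) {
  cat(sprintf("<moment_dataset> %d records, %d features (max order %d), %d dropped\n",
              nrow(x$records), length(feature_labels(x$max_order)),
              x$max_order, x$n_dropped))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' Hold out a random test split
#'
#' Labels `n_test` uniformly random records as the test set and the rest as
#' training, reproducibly for a given seed. Test records are never seen
#' during training; they serve exclusively to measure accuracy afterwards.
#'
#' @param dataset A `moment_dataset`.
#' @param n_test Number of records to hold out (< number of records).
#' @param seed Integer seed for the draw.
#' @return The dataset with its `split` factor set.
#' @export
split_dataset <- function(dataset, n_test, seed = 1) {
  stopifnot(inherits(dataset, "moment_dataset"))
  n <- nrow(dataset$records)
  if (n_test >= n) stop("`n_test` must be smaller than the record count")
  u <- derive_uniforms(seed, n)
  test_idx <- order(u)[seq_len(n_test)]
  split <- factor(rep("train", n), levels = c("train", "test"))
  split[test_idx] <- "test"
  dataset$split <- split
  dataset
}

# Deterministic integer seeds / uniforms derived from a master seed via the
# package's own counter-based generator (independent of R's global RNG).
derive_seeds <- function(master_seed, k) {
  floor(cpp_derive_uniforms(as.double(master_seed), as.integer(k), 1) *
          2147483647)
}

derive_uniforms <- function(master_seed, k) {
  cpp_derive_uniforms(as.double(master_seed), as.integer(k), 2)
}

#' Write / read a moment dataset as annotated CSV
#'
#' The file carries one commented JSON header line holding the generation
#' metadata (ranges, geometry, simulation configuration, master seed,
#' dropped-run count and split labels) followed by a plain CSV table with
#' one row per record, so it round-trips losslessly and stays readable by
#' any CSV tool.
#'
#' @param dataset A `moment_dataset`.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed `moment_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "moment_dataset"))
  meta <- list(
    ranges = unclass(dataset$ranges),
    geometry = unclass(dataset$geometry),
    sim_config = unclass(dataset$sim_config),
    master_seed = dataset$master_seed,
    max_order = dataset$max_order,
    n_dropped = dataset$n_dropped,
    split = if (is.null(dataset$split)) NULL else as.character(dataset$split))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  utils::write.csv(dataset$records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# "))
    stop("not a moment_dataset file: missing metadata header")
  meta <- jsonlite::fromJSON(substring(header, 3L))
  records <- utils::read.csv(path, comment.char = "#")
  structure(
    list(records = records,
         ranges = do.call(parameter_ranges, meta$ranges),
         geometry = do.call(slab_geometry, meta$geometry),
         sim_config = structure(meta$sim_config, class = "sim_config"),
         master_seed = as.numeric(meta$master_seed),
         max_order = as.integer(meta$max_order),
         n_dropped = meta$n_dropped,
         split = if (is.null(meta$split)) NULL else
           factor(meta$split, levels = c("train", "test"))),
    class = "moment_dataset")
}
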