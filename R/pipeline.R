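#' Default pipeline configuration
#'
#' A nested, fully serializable description of one end-to-end run: dataset
#' generation over the biological parameter ranges, train/test split, network
#' training and evaluation. Every random stage draws its substream from the
#' single `seed`, so a persisted configuration re-executes to identical
#' outputs.
#'
#' @param n_runs Monte Carlo runs to generate.
#' @param n_photons Photons per run.
#' @param n_test Records held out for testing.
#' @param hidden_size,epochs Network width and training epochs.
#' @param seed Master seed.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(n_runs = 1000, n_photons = 1e4, n_test = 200,
                               hidden_size = 150, epochs = 500, seed = 1) {
  structure(list(
    seed = seed,
    dataset = list(n_runs = n_runs, n_test = n_test, max_order = 5),
    ranges = unclass(parameter_ranges()),
    geometry = unclass(slab_geometry()),
    simulation = list(n_photons = n_photons, roulette_threshold = 1e-6,
                      roulette_m = 10, max_events = 1e6),
    network = list(hidden_size = hidden_size, epochs = epochs,
                   learning_rate = 1e-3, batch_size = 256,
                   n_hidden = 3)),
    class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  structure(base, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full estimation pipeline
#'
#' Executes dataset generation, the train/test split, network training and
#' test-split evaluation from one configuration, writing each artifact plus
#' a manifest (stage timings, record counts, configuration hash) into
#' `out_dir`. Re-running the same configuration reproduces the artifacts.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the `dataset`, `model`, `report` and the
#'   paths of the written artifacts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = ".",
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (config$dataset$n_test >= config$dataset$n_runs)
    stop("config error: n_test must be smaller than n_runs")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
  }

  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  sd <- stage("gen-data", {
    generate_dataset(
      n_runs = config$dataset$n_runs,
      ranges = do.call(parameter_ranges, config$ranges),
      geometry = do.call(slab_geometry, config$geometry),
      sim_config = sim_config(
        n_photons = config$simulation$n_photons,
        roulette_threshold = config$simulation$roulette_threshold,
        roulette_m = config$simulation$roulette_m,
        max_events = config$simulation$max_events),
      master_seed = config$seed,
      max_order = config$dataset$max_order)
  })
  dataset <- split_dataset(sd$value, n_test = config$dataset$n_test,
                           seed = config$seed + 1)
  say("gen-data: %d records (%d dropped) in %.1fs",
      nrow(dataset$records), dataset$n_dropped, sd$elapsed)

  tr <- stage("train", {
    train_inverse_model(
      dataset, hidden_size = config$network$hidden_size,
      epochs = config$network$epochs, seed = config$seed + 2,
      learning_rate = config$network$learning_rate,
      batch_size = config$network$batch_size,
      n_hidden = config$network$n_hidden)
  })
  say("train: %d epochs, final MSE %.3g in %.1fs",
      config$network$epochs, utils::tail(tr$value$training$loss_history, 1),
      tr$elapsed)

  ev <- stage("evaluate", evaluate_model(tr$value, dataset))
  say("evaluate: %d test records", ev$value$n_records)

  paths <- list(
    config = cfg_path,
    dataset = file.path(out_dir, "dataset.csv"),
    model = file.path(out_dir, "model.json"),
    report = file.path(out_dir, "report.csv"),
    summary = file.path(out_dir, "report_summary.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_dataset(dataset, paths$dataset)
  save_inverse_model(tr$value, paths$model)
  write_report(ev$value, paths$report, paths$summary)
  jsonlite::write_json(list(
    config_hash = config_hash,
    artifacts = lapply(paths[c("dataset", "model", "report", "summary")],
                       basename),
    n_records = nrow(dataset$records),
    n_dropped = dataset$n_dropped,
    n_test = ev$value$n_records,
    timings_s = list(gen_data = sd$elapsed, train = tr$elapsed,
                     evaluate = ev$elapsed)),
    paths$manifest, auto_unbox = TRUE, digits = I(6))

  invisible(list(dataset = dataset, model = tr$value, report = ev$value,
                 paths = paths))
}
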