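#' Per-sample standard error
#'
#' The accuracy measure used throughout:
#' `E = 100 * |truth - predicted| / truth`, a percentage computed on the
#' linear scale for all three parameters (even though the network trains on
#' log-scale targets for the two coefficients).
#'
#' @param truth True value(s), non-zero.
#' @param predicted Predicted value(s).
#' @return Percentage error(s), >= 0.
#' @examples
#' standard_error(2, 1)      # 50
#' standard_error(0.1, 0.13) # 30
#' @export
standard_error <- function(truth, predicted) {
  if (any(truth == 0)) stop("`truth` must be non-zero")
  100 * abs(truth - predicted) / abs(truth)
}

#' Confidence level of an error distribution
#'
#' The q% confidence level is the error value below which q% of the samples
#' fall: the q-th percentile of the per-sample errors, computed with linear
#' interpolation between order statistics (a pinned convention so reported
#' levels are reproducible).
#'
#' @param errors Non-empty numeric vector of percentage errors.
#' @param q Percentile, default 95.
#' @return The q-th percentile of `errors`.
#' @examples
#' confidence_level(1:100)  # 95.05
#' @export
confidence_level <- function(errors, q = 95) {
  if (length(errors) == 0L) stop("`errors` must be non-empty")
  if (any(!is.finite(errors))) stop("`errors` must be finite")
  unname(stats::quantile(errors, q / 100, type = 7))
}

#' Evaluate a trained inverse model on the held-out split
#'
#' Predicts every test record, computes the per-sample standard error for
#' each parameter (`n`, `mu_s'`, `mu_a`) on the linear scale, and summarizes
#' each with its median, mean and 95% confidence level. The returned tables
#' are keyed by the truth values so prediction-versus-truth and
#' error-versus-truth plots can be drawn directly.
#'
#' @param model An `inverse_model`.
#' @param dataset A `moment_dataset`. By default its test split is
#'   evaluated (requiring [split_dataset()] to have run); set
#'   `split = "train"` for consistency checks on the training split.
#' @param split Which split to evaluate, `"test"` (default) or `"train"`.
#' @return An object of class `evaluation_report`: a list with `predictions`
#'   (data frame: `run_id`, truth, predicted and error columns per
#'   parameter) and `summary` (data frame: one row per parameter with
#'   `median_error`, `mean_error`, `ci95`, in percent) plus `n_records`.
#' @export
evaluate_model <- function(model, dataset, split = c("test", "train")) {
  split <- match.arg(split)
  stopifnot(inherits(model, "inverse_model"),
            inherits(dataset, "moment_dataset"))
  if (is.null(dataset$split) && split == "test")
    stop("dataset has no test split; run split_dataset() first")
  rec <- dataset$records
  if (!is.null(dataset$split)) rec <- rec[dataset$split == split, ,
                                          drop = FALSE]
  if (nrow(rec) == 0L) stop("no records in the requested split")

  pred <- predict(model, rec)
  params <- c("n", "mu_s_prime", "mu_a")
  errs <- lapply(params, function(p) standard_error(rec[[p]], pred[[p]]))
  names(errs) <- params

  predictions <- data.frame(
    run_id = rec$run_id,
    n_truth = rec$n, n_pred = pred$n, n_error = errs$n,
    mu_s_prime_truth = rec$mu_s_prime, mu_s_prime_pred = pred$mu_s_prime,
    mu_s_prime_error = errs$mu_s_prime,
    mu_a_truth = rec$mu_a, mu_a_pred = pred$mu_a, mu_a_error = errs$mu_a)

  summary <- data.frame(
    parameter = params,
    median_error = vapply(errs, stats::median, numeric(1)),
    mean_error = vapply(errs, mean, numeric(1)),
    ci95 = vapply(errs, confidence_level, numeric(1)),
    row.names = NULL)

  structure(list(predictions = predictions, summary = summary,
                 n_records = nrow(rec), split = split),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d %s records\n", x$n_records, x$split))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s median %6.2f%%   mean %7.2f%%   95%% level %7.2f%%\n",
                s$parameter[i], s$median_error[i], s$mean_error[i],
                s$ci95[i]))
  invisible(x)
}

#' Export an evaluation report to CSV
#'
#' Writes the per-record prediction table and, optionally, the parameter
#' summary as plain CSV files.
#'
#' @param report An `evaluation_report`.
#' @param path Output CSV path for the per-record table.
#' @param summary_path Optional path for the summary table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.csv(report$predictions, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(report$summary, summary_path, row.names = FALSE)
  invisible(path)
}
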