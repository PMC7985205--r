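#' Canonical moment index order
#'
#' Enumerates the radial/temporal moment orders `(alpha, beta)` with
#' `alpha + beta <= max_order`, in canonical order: total order ascending,
#' and within a total order alpha descending. The first three slots are the
#' non-central quantities `W` (total detected weight, order 0) and the
#' weighted means `<r>`, `<t>` (order 1); every slot with total order >= 2
#' is a weighted central cross-moment. With `max_order = 5` there are 21
#' entries, the feature vector used for inversion.
#'
#' @param max_order Highest total moment order (integer >= 0, default 5).
#' @return A data frame with integer columns `alpha`, `beta` and a `label`
#'   column (`"W"`, `"r_mean"`, `"t_mean"`, then `"m_<alpha>_<beta>"`), with
#'   `(max_order + 1) * (max_order + 2) / 2` rows.
#' @examples
#' nrow(moment_indices(5))  # 21
#' @export
moment_indices <- function(max_order = 5L) {
  if (!is.numeric(max_order) || length(max_order) != 1L ||
      max_order < 0 || max_order != floor(max_order))
    stop("`max_order` must be a non-negative integer")
  ord <- do.call(rbind, lapply(0:max_order, function(k)
    data.frame(alpha = k:0, beta = 0:k)))
  ord$label <- ifelse(
    ord$alpha + ord$beta == 0L, "W",
    ifelse(ord$alpha == 1L & ord$beta == 0L, "r_mean",
    ifelse(ord$alpha == 0L & ord$beta == 1L, "t_mean",
           sprintf("m_%d_%d", ord$alpha, ord$beta))))
  ord
}

#' Spatio-temporal moments of an exit log
#'
#' Compresses the photon exit log of one simulation into the ordered vector
#' of weighted spatio-temporal moments of the detected distribution
#' \eqn{I(r, t)}. The zeroth-order slot is the total detected weight
#' \eqn{W = \sum_i w_i}; the first-order slots are the weighted means
#' \eqn{\langle r\rangle} and \eqn{\langle t\rangle}; every higher slot is
#' the weighted central cross-moment
#' \eqn{\langle r^\alpha t^\beta\rangle =
#'   \sum_i w_i (r_i - \langle r\rangle)^\alpha
#'            (t_i - \langle t\rangle)^\beta / W}.
#' Records are summed in a fixed order (sorted by arrival time, then radius)
#' so the result is deterministic regardless of input ordering.
#'
#' @param exit_records Data frame of exit records with at least columns
#'   `side`, `r`, `weight`, `time`, or a `simulation_result` (whose specular
#'   record is then available to `include_specular`).
#' @param max_order Highest total moment order (default 5, giving 21 values).
#' @param side Which detector to featurize: `"reflection"` (default; the
#'   inversion operates in the reflection geometry) or `"transmission"`.
#' @param include_specular Include the deterministic specular record when a
#'   `simulation_result` is given. Default `TRUE`: every exiting photon is
#'   part of the logged response.
#' @return An object of class `feature_vector`: a named numeric vector of
#'   length `(max_order + 1)(max_order + 2)/2` with attributes `indices`
#'   (the [moment_indices()] table), `max_order`, `side` and `valid`. An
#'   empty detector (`W = 0`) yields `valid = FALSE` and all-`NA` values,
#'   never silent zeros.
#' @examples
#' rec <- data.frame(side = "reflection", r = c(0, 2), weight = c(1, 1),
#'                   time = c(10, 10))
#' compute_moments(rec, max_order = 2)
#' @export
compute_moments <- function(exit_records, max_order = 5L,
                            side = c("reflection", "transmission"),
                            include_specular = TRUE) {
  side <- match.arg(side)
  if (inherits(exit_records, "simulation_result")) {
    rec <- exit_records$exit_records
    if (include_specular && !is.null(exit_records$specular_record))
      rec <- rbind(exit_records$specular_record, rec)
  } else {
    rec <- exit_records
  }
  stopifnot(is.data.frame(rec),
            all(c("side", "r", "weight", "time") %in% names(rec)))
  rec <- rec[rec$side == side, , drop = FALSE]
  idx <- moment_indices(max_order)

  out <- rep(NA_real_, nrow(idx))
  names(out) <- idx$label
  valid <- nrow(rec) > 0 && sum(rec$weight) > 0
  if (valid) {
    rec <- rec[order(rec$time, rec$r), , drop = FALSE]
    w <- rec$weight
    r <- rec$r
    t <- rec$time
    W <- sum(w)
    r_mean <- sum(w * r) / W
    t_mean <- sum(w * t) / W
    dr <- r - r_mean
    dt <- t - t_mean
    for (k in seq_len(nrow(idx))) {
      a <- idx$alpha[k]; b <- idx$beta[k]
      tot <- a + b
      out[k] <- if (tot == 0L) W
        else if (tot == 1L) (if (a == 1L) r_mean else t_mean)
        else sum(w * dr^a * dt^b) / W
    }
  }
  structure(out, indices = idx, max_order = as.integer(max_order),
            side = side, valid = valid, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d moments (max order %d, %s side, %s)\n",
              length(x), attr(x, "max_order"), attr(x, "side"),
              if (attr(x, "valid")) "valid" else "INVALID: empty detector"))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Labels of the canonical feature columns
#'
#' @param max_order Highest total moment order (default 5).
#' @return Character vector of feature labels in canonical order.
#' @export
feature_labels <- function(max_order = 5L) moment_indices(max_order)$label
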