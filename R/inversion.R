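#' Min-max target scaler
#'
#' The network regresses on targets normalized to `[0, 1]` by
#' `(X - min(X)) / (max(X) - min(X))`, where `X` is `n`, `log10(mu_s')` or
#' `log10(mu_a)`: the two transport coefficients are log-transformed before
#' scaling because they span several decades. Fitted on the training split
#' only and applied unchanged to test data.
#'
#' @param targets Data frame or matrix with columns `n`, `mu_s_prime`,
#'   `mu_a` (linear scale).
#' @return An object of class `target_scaler` with per-target `min`/`max`
#'   on the transformed scale.
#' @export
fit_target_scaler <- function(targets) {
  m <- transform_targets(targets)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  if (any(hi - lo <= 0))
    stop("degenerate target scaler: min equals max for ",
         paste(colnames(m)[hi - lo <= 0], collapse = ", "))
  structure(list(min = lo, max = hi), class = "target_scaler")
}

transform_targets <- function(targets) {
  targets <- as.data.frame(targets)
  stopifnot(all(c("n", "mu_s_prime", "mu_a") %in% names(targets)))
  cbind(n = targets$n,
        log_mu_s_prime = log10(targets$mu_s_prime),
        log_mu_a = log10(targets$mu_a))
}

#' Normalize optical-property targets to the unit cube (and back)
#'
#' @param truth An [optical_properties()] object or a data frame with
#'   columns `n`, `mu_s_prime`, `mu_a`.
#' @param scaler A fitted `target_scaler`.
#' @return `normalize_targets` returns a matrix with columns in `[0, 1]`
#'   (`n`, `log_mu_s_prime`, `log_mu_a`); `denormalize_targets` inverts both
#'   the scaling and the log transform, returning columns `n`, `mu_s_prime`,
#'   `mu_a` on the linear scale.
#' @examples
#' sc <- fit_target_scaler(
#'   data.frame(n = c(1.3, 1.6), mu_s_prime = c(0.05, 50),
#'              mu_a = c(0.01, 10)))
#' normalize_targets(data.frame(n = 1.45, mu_s_prime = 1, mu_a = 0.1), sc)
#' @export
normalize_targets <- function(truth, scaler) {
  stopifnot(inherits(scaler, "target_scaler"))
  if (inherits(truth, "optical_properties"))
    truth <- data.frame(n = truth$n, mu_s_prime = truth$mu_s_prime,
                        mu_a = truth$mu_a)
  m <- transform_targets(truth)
  sweep(sweep(m, 2, scaler$min), 2, scaler$max - scaler$min, "/")
}

#' @rdname normalize_targets
#' @param scaled Matrix of values on the normalized scale.
#' @export
denormalize_targets <- function(scaled, scaler) {
  stopifnot(inherits(scaler, "target_scaler"))
  scaled <- matrix(scaled, ncol = 3L)
  m <- sweep(sweep(scaled, 2, scaler$max - scaler$min, "*"), 2,
             scaler$min, "+")
  out <- cbind(n = m[, 1], mu_s_prime = 10^m[, 2], mu_a = 10^m[, 3])
  out
}

fit_feature_scaler <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  scale <- hi - lo
  scale[scale <= 0] <- 1  # constant feature maps to 0
  structure(list(min = lo, scale = scale), class = "feature_scaler")
}

apply_feature_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$min), 2, scaler$scale, "/")
}

# optional symmetric log compression for features spanning decades
signed_log <- function(x) sign(x) * log10(1 + abs(x))

#' Train the moment-to-property inverse network
#'
#' Fits a fully connected network of shape `[n_features, x, x, x, 3]` (ReLU
#' hidden layers, linear output) mapping the canonical moment features to
#' the normalized targets `n`, `log10(mu_s')`, `log10(mu_a)`, by Adam on
#' mean squared error over shuffled mini-batches. Features are min-max
#' scaled per feature using training-split statistics; target scaling
#' follows [fit_target_scaler()]. Training runs for the full epoch budget
#' with no early stopping; the per-epoch loss history is kept. The test
#' split, when present, is never touched.
#'
#' @param dataset A `moment_dataset`, normally after [split_dataset()];
#'   without a split every record trains.
#' @param hidden_size Width `x` of each of the three hidden layers
#'   (default 150).
#' @param epochs Number of passes over the training split (default 5000;
#'   scaled-down runs may use fewer).
#' @param seed Integer seed fixing weight initialization and batch order.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 256).
#' @param signed_log_features Apply a signed-log compression
#'   `sign(x) log10(1 + |x|)` to features before scaling. Default `FALSE`.
#' @param n_hidden Number of hidden layers (default 3).
#' @return An object of class `inverse_model` holding layer sizes, weights,
#'   biases, both scalers, and training metadata including the loss history.
#' @export
train_inverse_model <- function(dataset, hidden_size = 150, epochs = 5000,
                                seed = 1, learning_rate = 1e-3,
                                batch_size = 256,
                                signed_log_features = FALSE,
                                n_hidden = 3L) {
  stopifnot(inherits(dataset, "moment_dataset"), hidden_size >= 1,
            epochs >= 1, n_hidden >= 1)
  labels <- feature_labels(dataset$max_order)
  rec <- dataset$records
  if (!is.null(dataset$split)) rec <- rec[dataset$split == "train", ,
                                          drop = FALSE]
  X <- as.matrix(rec[, labels, drop = FALSE])
  if (any(!is.finite(X))) {
    bad <- rec$run_id[!stats::complete.cases(X) |
                        apply(!is.finite(X), 1, any)]
    stop("non-finite features in records: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (signed_log_features) X <- signed_log(X)
  feature_scaler <- fit_feature_scaler(X)
  Xs <- apply_feature_scaler(X, feature_scaler)
  target_scaler <- fit_target_scaler(rec)
  Ys <- normalize_targets(rec, target_scaler)

  fit <- cpp_train_mlp(Xs, Ys, rep(as.integer(hidden_size), n_hidden),
                       as.integer(epochs), as.integer(batch_size),
                       learning_rate, as.double(seed))
  structure(
    list(layer_sizes = c(ncol(X), rep(hidden_size, n_hidden), 3L),
         weights = fit$weights, biases = fit$biases,
         activation = "relu", output = "linear",
         feature_labels = labels,
         signed_log_features = isTRUE(signed_log_features),
         feature_scaler = feature_scaler, target_scaler = target_scaler,
         training = list(epochs = epochs, seed = seed,
                         learning_rate = learning_rate,
                         batch_size = batch_size,
                         n_train = nrow(X),
                         loss_history = fit$loss_history)),
    class = "inverse_model")
}

#' @export
print.inverse_model <- function(x, ...) {
  cat(sprintf("<inverse_model> [%s] %s hidden, trained %d epochs on %d records (final MSE %.3g)\n",
              paste(x$layer_sizes, collapse = ", "), x$activation,
              x$training$epochs, x$training$n_train,
              utils::tail(x$training$loss_history, 1)))
  invisible(x)
}

#' Predict optical properties from moment features
#'
#' Applies the trained network to one or more feature vectors: features are
#' scaled with the training statistics, passed through the network, and the
#' outputs inverse-transformed (affine un-scaling, then `10^x` for the two
#' coefficients), so `mu_s'` and `mu_a` are strictly positive by
#' construction. Predictions are made record by record internally, so a
#' batch call is element-wise identical to single calls. Out-of-range
#' predictions are reported as-is, never clipped.
#'
#' @param object An `inverse_model`.
#' @param features A `feature_vector`, a numeric matrix, or a data frame
#'   containing the model's feature columns.
#' @param ... Unused.
#' @return A data frame with columns `n`, `mu_s_prime`, `mu_a`.
#' @export
predict.inverse_model <- function(object, features, ...) {
  X <- coerce_features(object, features)
  if (any(!is.finite(X)))
    stop("non-finite feature values; cannot predict")
  if (object$signed_log_features) X <- signed_log(X)
  Xs <- apply_feature_scaler(X, object$feature_scaler)
  raw <- cpp_mlp_forward(Xs, object$weights, object$biases)
  as.data.frame(denormalize_targets(raw, object$target_scaler))
}

coerce_features <- function(model, features) {
  labels <- model$feature_labels
  if (inherits(features, "feature_vector")) {
    if (!attr(features, "valid"))
      stop("invalid feature vector (empty detector); cannot predict")
    features <- matrix(as.numeric(features), nrow = 1L,
                       dimnames = list(NULL, names(features)))
  }
  if (is.data.frame(features)) features <- as.matrix(features[, labels,
                                                              drop = FALSE])
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (!is.null(colnames(features)))
    features <- features[, labels, drop = FALSE]
  if (ncol(features) != length(labels))
    stop(sprintf("expected %d features, got %d", length(labels),
                 ncol(features)))
  features
}

#' Save / load a trained inverse model
#'
#' The model is written as a self-describing JSON file carrying the
#' architecture, activation, both scalers, all weights at full double
#' precision and the training metadata; nothing framework-private. A
#' load/save round trip reproduces predictions bit-exactly.
#'
#' @param model An `inverse_model`.
#' @param path File path (conventionally `.json`).
#' @return `save_inverse_model` returns `path` invisibly;
#'   `load_inverse_model` returns the model.
#' @export
save_inverse_model <- function(model, path) {
  stopifnot(inherits(model, "inverse_model"))
  payload <- list(
    format = "tissueoptics-inverse-model",
    version = 1L,
    layer_sizes = model$layer_sizes,
    activation = model$activation, output = model$output,
    feature_labels = model$feature_labels,
    signed_log_features = model$signed_log_features,
    feature_scaler = unclass(model$feature_scaler),
    target_scaler = lapply(unclass(model$target_scaler), as.list),
    weights = model$weights, biases = model$biases,
    training = model$training)
  # I(17) = 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_inverse_model
#' @export
load_inverse_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(p$format, "tissueoptics-inverse-model"))
    stop("not a tissueoptics inverse-model file")
  sizes <- as.numeric(p$layer_sizes)
  weights <- lapply(p$weights, function(w) {
    w <- as.matrix(w)
    storage.mode(w) <- "double"
    dimnames(w) <- NULL
    w
  })
  biases <- lapply(p$biases, as.numeric)
  structure(
    list(layer_sizes = sizes, weights = weights, biases = biases,
         activation = p$activation, output = p$output,
         feature_labels = p$feature_labels,
         signed_log_features = isTRUE(p$signed_log_features),
         feature_scaler = structure(
           list(min = stats::setNames(as.numeric(p$feature_scaler$min),
                                      p$feature_labels),
                scale = stats::setNames(as.numeric(p$feature_scaler$scale),
                                        p$feature_labels)),
           class = "feature_scaler"),
         target_scaler = structure(
           list(min = unlist(p$target_scaler$min),
                max = unlist(p$target_scaler$max)),
           class = "target_scaler"),
         training = p$training),
    class = "inverse_model")
}
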