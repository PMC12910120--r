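#' Network specification for a parameter-recovery model
#'
#' Default architecture: an input layer of 10 features, six densely
#' connected hidden layers of 128 ReLU units each, and a single linear
#' output unit (84,097 trainable parameters), trained with RMSprop on
#' mean squared error with z-score feature standardization, shuffling, a
#' validation split and early stopping.
#'
#' @param n_features Input width (default 10).
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSprop learning rate.
#' @param rho RMSprop decay of the squared-gradient average.
#' @param epsilon RMSprop numerical stabilizer.
#' @param decay Per-epoch learning-rate decay:
#'   `lr_epoch = learning_rate / (1 + decay * epoch)`; 0 keeps the rate
#'   constant.
#' @param validation_split Fraction of training rows held out for
#'   validation-loss monitoring.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); best weights are restored.
#' @return List of class `mlp_spec`.
#' @examples
#' count_params(mlp_spec())
#' @export
mlp_spec <- function(n_features = 10, hidden = rep(128L, 6), epochs = 200,
                     batch_size = 512, learning_rate = 0.001, rho = 0.9,
                     epsilon = 1e-7, decay = 0, validation_split = 0.1,
                     patience = 10) {
  stopifnot(n_features >= 1, all(hidden >= 1) || length(hidden) == 0,
            epochs >= 1, batch_size >= 1)
  structure(list(
    n_features = as.integer(n_features), hidden = as.integer(hidden),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, rho = rho, epsilon = epsilon,
    decay = decay, validation_split = validation_split,
    patience = as.integer(patience)
  ), class = "mlp_spec")
}

#' Count trainable parameters of a network specification
#'
#' Analytic count: weights plus biases across all dense layers.
#'
#' @param spec An [mlp_spec()].
#' @return Integer parameter count (84,097 for the default specification).
#' @examples
#' count_params(mlp_spec(hidden = 64))
#' @export
count_params <- function(spec = mlp_spec()) {
  widths <- c(spec$n_features, spec$hidden, 1L)
  sum(widths[-length(widths)] * widths[-1] + widths[-1])
}

#' Train a recovery model for one target parameter
#'
#' Standardizes the ten monitoring features to z-scores (statistics from
#' the training rows), then trains the network of `spec` to regress the
#' target on its raw scale. Deterministic under a fixed R random seed.
#'
#' @param data Tibble containing the feature columns
#'   ([monitoring_features()]) and the target column.
#' @param target One of `"shunt"`, `"logsd"`, `"meanvq"` (any numeric
#'   column works).
#' @param spec An [mlp_spec()].
#' @param features Feature column names.
#' @return Object of class `recovery_fit`: weights, normalization
#'   statistics, training history and the training-data target range used
#'   for out-of-range flagging.
#' @examples
#' \donttest{
#' set.seed(7)
#' cohort <- generate_cohort(2000, role = "train")
#' fit <- fit_recovery(cohort, "shunt", mlp_spec(epochs = 5))
#' glance(fit)
#' }
#' @export
fit_recovery <- function(data, target, spec = mlp_spec(),
                         features = monitoring_features()) {
  missing_cols <- setdiff(c(features, target), names(data))
  if (length(missing_cols) > 0) {
    stop("`data` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[features])
  y <- data[[target]]
  stopifnot(nrow(X) >= 10, !anyNA(X), !anyNA(y))
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  fitted <- cpp_mlp_train(Xs, y, spec$hidden, spec$epochs, spec$batch_size,
                          spec$learning_rate, spec$rho, spec$epsilon,
                          spec$decay %||% 0, spec$validation_split,
                          spec$patience)
  if (!all(is.finite(unlist(fitted$loss)))) {
    stop("training diverged: non-finite loss (history attached)",
         call. = FALSE)
  }
  structure(list(
    target = target, features = features, spec = spec,
    weights = fitted$weights, biases = fitted$biases,
    center = mu, scale = sigma,
    history = tibble::tibble(
      epoch = seq_along(fitted$loss),
      loss = unlist(fitted$loss),
      val_loss = if (length(fitted$val_loss)) unlist(fitted$val_loss)
                 else NA_real_
    ),
    best_epoch = fitted$best_epoch,
    n_train = fitted$n_train, n_val = fitted$n_val,
    target_range = range(y)
  ), class = "recovery_fit")
}

#' Predict a recovered parameter
#'
#' Applies the stored feature standardization, then the network. Values
#' outside the training-data target range are returned unaltered but
#' flagged through the `out_of_range` attribute (never silently clipped).
#'
#' @param object A `recovery_fit`.
#' @param newdata Tibble carrying the feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions with a logical `out_of_range`
#'   attribute.
#' @export
predict.recovery_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    stop("`newdata` lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[object$features])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pred <- as.numeric(cpp_mlp_predict(object$weights, object$biases, Xs))
  attr(pred, "out_of_range") <-
    pred < object$target_range[1] | pred > object$target_range[2]
  pred
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> target: %s, %s params, trained %d epochs\n",
              x$target, format(count_params(x$spec), big.mark = ","),
              nrow(x$history)))
  invisible(x)
}

#' @describeIn fit_recovery Per-epoch training history as a tibble.
#' @param x,object A `recovery_fit`.
#' @param ... Unused.
#' @export
tidy.recovery_fit <- function(x, ...) x$history

#' @describeIn fit_recovery One-row training summary (final and best
#'   losses, epochs run, parameter count).
#' @export
glance.recovery_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    target = x$target,
    n_params = count_params(x$spec),
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    final_loss = h$loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)],
    n_train = x$n_train, n_val = x$n_val
  )
}

#' @describeIn fit_recovery Bind predictions (`.pred`) and the
#'   out-of-range flag (`.out_of_range`) onto `data`.
#' @param data Tibble with feature columns (for `augment`).
#' @export
augment.recovery_fit <- function(x, data, ...) {
  p <- predict(x, data)
  data$.pred <- as.numeric(p)
  data$.out_of_range <- attr(p, "out_of_range")
  data
}
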