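#' Plot ranked mean absolute Shapley attributions
#'
#' Horizontal bar chart of mean |SHAP| per monitoring feature, most
#' important at the top.
#'
#' @param object A `shap_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shap_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$mean_abs_shap,
    y = stats::reorder(.data$feature, .data$mean_abs_shap))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "mean |SHAP value|", y = NULL,
      title = paste0("Feature sensitivity: ",
                     object$target %||% "prediction")) +
    ggplot2::theme_minimal()
}

#' Plot training history of a recovery model
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch", names_to = "series",
                           values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste("Training history:", object$target),
                  y = "mean squared error") +
    ggplot2::theme_minimal()
}

#' Overlaid density estimates of true and predicted parameter values
#'
#' Scott-rule KDEs of the true and predicted distributions on a common
#' axis, the graphical check that the recovered distribution tracks the
#' generating one.
#'
#' @param data Tibble with truth and prediction columns.
#' @param truth,pred Column names.
#' @param label Axis label for the parameter.
#' @return A ggplot object.
#' @export
plot_prediction_density <- function(data, truth, pred = ".pred",
                                    label = truth) {
  kt <- kde_scott(data[[truth]])
  kp <- kde_scott(data[[pred]])
  d <- dplyr::bind_rows(
    tibble::tibble(x = kt$x, density = kt$density, series = "true"),
    tibble::tibble(x = kp$x, density = kp$density, series = "predicted")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$density,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = label, y = "density") +
    ggplot2::theme_minimal()
}

#' Prediction error versus FiO2 with a 95% density contour
#'
#' Bivariate Scott-rule KDE of prediction error against inspired oxygen
#' fraction; the drawn contour encloses 95% of the points and the
#' horizontal line marks zero error.
#'
#' @param data Tibble with truth, prediction and `fio2` columns.
#' @param truth,pred Column names.
#' @param prob Contour coverage probability.
#' @return A ggplot object.
#' @export
plot_error_vs_fio2 <- function(data, truth, pred = ".pred", prob = 0.95) {
  err <- data[[pred]] - data[[truth]]
  k <- kde2d_scott(data$fio2, err)
  lev <- kde_contour_level(k, data$fio2, err, prob = prob)
  grid <- expand.grid(fio2 = k$x, error = k$y)
  grid$z <- as.vector(k$z)
  ggplot2::ggplot(grid, ggplot2::aes(.data$fio2, .data$error)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), breaks = lev,
                          colour = "black") +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::labs(x = "FiO2", y = paste("error in", truth)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
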