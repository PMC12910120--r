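#' Univariate regression of predicted versus true parameter values
#'
#' Ordinary least squares with the *predicted* value as the dependent
#' variable and the true ("gold standard") value as the independent
#' variable. Reports the slope with its 95% confidence interval, the
#' p-value and the coefficient of determination.
#'
#' @param data Tibble holding the prediction and truth columns.
#' @param pred,truth Column names (strings) of predicted and true values.
#' @param target Optional label for the parameter being assessed.
#' @return Object of class `recovery_regression` wrapping the `lm` fit.
#' @examples
#' d <- tibble::tibble(true = 1:10, est = 1:10 + rnorm(10, sd = 0.1))
#' tidy(regress_pred_vs_true(d, "est", "true"))
#' @export
regress_pred_vs_true <- function(data, pred = ".pred", truth,
                                 target = truth) {
  x <- data[[truth]]
  y <- data[[pred]]
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) < 1e-14) {
    stop("degenerate regression: zero variance in the true values",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  structure(list(fit = fit, target = target, n = length(x)),
            class = "recovery_regression")
}

#' @export
print.recovery_regression <- function(x, ...) {
  t <- tidy(x)
  cat(sprintf(
    "<recovery_regression> %s: beta %.4f [%.4f, %.4f], R^2 %.4f, n %d\n",
    x$target, t$estimate, t$conf.low, t$conf.high, t$r.squared, x$n))
  invisible(x)
}

#' @describeIn regress_pred_vs_true One-row tibble: slope, 95% CI,
#'   p-value, R squared, n.
#' @param x A `recovery_regression`.
#' @param ... Unused.
#' @export
tidy.recovery_regression <- function(x, ...) {
  s <- summary(x$fit)
  ci <- confint(x$fit, "x", level = 0.95)
  tibble::tibble(
    target = x$target,
    term = "slope",
    estimate = unname(coef(x$fit)["x"]),
    conf.low = ci[1], conf.high = ci[2],
    p.value = s$coefficients["x", "Pr(>|t|)"],
    r.squared = s$r.squared,
    n = x$n
  )
}

#' @describeIn regress_pred_vs_true Model-level summary (R squared, sigma,
#'   n).
#' @export
glance.recovery_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(target = x$target, r.squared = s$r.squared,
                 sigma = s$sigma, n = x$n)
}

#' Scott-rule bandwidth
#'
#' `sd(x) * n^(-1/(d + 4))`: the Gaussian-kernel smoothing bandwidth of
#' Scott's rule for a d-dimensional estimate.
#'
#' @param x Numeric sample.
#' @param d Dimensionality of the estimate the bandwidth is used in.
#' @return Bandwidth (kernel standard deviation) on the scale of `x`.
#' @examples
#' scott_bandwidth(rnorm(1000))
#' @export
scott_bandwidth <- function(x, d = 1) {
  sd(x) * length(x)^(-1 / (d + 4))
}

#' Univariate Gaussian kernel density estimate (Scott rule)
#'
#' @param x Numeric sample (n >= 20).
#' @param n_grid Number of evaluation points.
#' @return Tibble of class `westvq_kde` with columns `x`, `density`;
#'   attribute `bw` carries the bandwidth.
#' @examples
#' kde_scott(rnorm(500))
#' @export
kde_scott <- function(x, n_grid = 512) {
  stopifnot(length(x) >= 20)
  if (sd(x) < 1e-14) {
    stop("degenerate KDE: zero-variance input", call. = FALSE)
  }
  bw <- scott_bandwidth(x, d = 1)
  d <- density(x, bw = bw, kernel = "gaussian", n = n_grid)
  structure(tibble::tibble(x = d$x, density = d$y), bw = bw,
            class = c("westvq_kde", "tbl_df", "tbl", "data.frame"))
}

#' Bivariate Gaussian kernel density estimate (Scott rule)
#'
#' Gaussian product kernel with per-axis Scott bandwidths
#' `sd * n^(-1/6)`, evaluated on a regular grid.
#'
#' @param x,y Numeric samples of equal length (n >= 20).
#' @param n_grid Grid points per axis.
#' @param expand Fractional range expansion of the evaluation window.
#' @return List of class `westvq_kde2d` with `x`, `y` (grid axes), `z`
#'   (density matrix) and `bw` (the two bandwidths).
#' @export
kde2d_scott <- function(x, y, n_grid = 121, expand = 0.15) {
  stopifnot(length(x) == length(y), length(x) >= 20)
  if (sd(x) < 1e-14 || sd(y) < 1e-14) {
    stop("degenerate KDE: zero-variance input", call. = FALSE)
  }
  n <- length(x)
  bw <- c(sd(x), sd(y)) * n^(-1 / 6)
  pad <- expand * c(diff(range(x)), diff(range(y)))
  lims <- c(range(x) + c(-1, 1) * pad[1], range(y) + c(-1, 1) * pad[2])
  # MASS::kde2d divides its h by 4 internally relative to a Gaussian sd
  k <- MASS::kde2d(x, y, h = 4 * bw, n = n_grid, lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bw = bw, n = n),
            class = "westvq_kde2d")
}

#' Density contour level containing a given fraction of the sample
#'
#' Interpolates the fitted density at each sample point and returns the
#' level below which the stated fraction of points would fall outside;
#' drawing the contour at this level encloses `prob` of the sample.
#'
#' @param kde A `westvq_kde2d`.
#' @param x,y The sample (typically the one the KDE was fitted to).
#' @param prob Fraction of points the contour should contain.
#' @return Density level (scalar).
#' @export
kde_contour_level <- function(kde, x, y, prob = 0.95) {
  stopifnot(inherits(kde, "westvq_kde2d"))
  dens <- interp_grid(kde$x, kde$y, kde$z, x, y)
  unname(quantile(dens, 1 - prob, type = 7))
}

# bilinear interpolation of a grid surface at scattered points
interp_grid <- function(gx, gy, gz, px, py) {
  ix <- findInterval(px, gx, all.inside = TRUE)
  iy <- findInterval(py, gy, all.inside = TRUE)
  tx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (py - gy[iy]) / (gy[iy + 1] - gy[iy])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  gz[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    gz[cbind(ix + 1, iy)] * tx * (1 - ty) +
    gz[cbind(ix, iy + 1)] * (1 - tx) * ty +
    gz[cbind(ix + 1, iy + 1)] * tx * ty
}

#' Exact Shapley-value sensitivity analysis
#'
#' Quantifies how much each monitoring feature moves a model's prediction
#' away from the background expectation, using exact Shapley values: with
#' ten features all 2^10 coalitions are enumerated, the value of a
#' coalition being the model's mean prediction when absent features are
#' replaced by background (calibration) draws. Attributions are exactly
#' additive: for every sample they sum to the prediction minus the
#' background mean prediction.
#'
#' @param model A `recovery_fit`, any object with a `predict` method
#'   accepting a data frame of features, or a plain function mapping such a
#'   data frame to numeric predictions.
#' @param analysis Tibble of samples to explain.
#' @param calibration Tibble of background samples; must be disjoint from
#'   `analysis`.
#' @param features Feature columns.
#' @param n_background Number of background rows drawn from `calibration`
#'   to represent the data distribution (the full calibration set is
#'   summarized by an i.i.d. subsample).
#' @param chunk Analysis rows processed per prediction batch.
#' @return Object of class `shap_report`: matrix `values` (samples x
#'   features), `base_value` (background mean prediction), `predictions`,
#'   and sizes.
#' @examples
#' \donttest{
#' set.seed(11)
#' cohort <- generate_cohort(3000, role = "train")
#' fit <- fit_recovery(cohort, "shunt", mlp_spec(epochs = 3))
#' rep <- shap_values(fit, cohort[1:20, ], cohort[21:500, ])
#' tidy(rep)
#' }
#' @export
shap_values <- function(model, analysis, calibration,
                        features = monitoring_features(),
                        n_background = 25, chunk = 32) {
  if (nrow(dplyr::semi_join(analysis, calibration, by = features)) > 0) {
    stop("analysis and calibration subsets must be mutually exclusive",
         call. = FALSE)
  }
  predict_fun <- if (is.function(model)) model else {
    function(d) predict(model, d)
  }
  p <- length(features)
  stopifnot(p <= 20)
  bg_idx <- sample.int(nrow(calibration), min(n_background,
                                              nrow(calibration)))
  B <- as.matrix(calibration[bg_idx, features])
  A <- as.matrix(analysis[, features])
  nb <- nrow(B)
  n <- nrow(A)

  # coalition masks: 2^p x p, bit j of m set <=> feature j present
  n_coal <- 2L^p
  masks <- matrix(FALSE, n_coal, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  sizes <- rowSums(masks)
  # Shapley kernel weight for the marginal contribution S -> S + {j},
  # |S| = k: k! (p - k - 1)! / p!
  wk <- exp(lgamma(0:(p - 1) + 1) + lgamma(p - (0:(p - 1))) - lgamma(p + 1))

  phi <- matrix(0, n, p, dimnames = list(NULL, features))
  vfull <- numeric(n)
  base <- NA_real_
  # big design matrix per chunk: (chunk * n_coal * nb) rows
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    m <- length(idx)
    # rows ordered: analysis sample (slowest), coalition, background
    big <- B[rep(rep(seq_len(nb), times = n_coal), times = m), ,
             drop = FALSE]
    sel <- rep(seq_len(n_coal), each = nb)
    arep <- A[rep(idx, each = n_coal * nb), , drop = FALSE]
    msk <- masks[rep(sel, times = m), , drop = FALSE]
    big[msk] <- arep[msk]
    preds <- predict_fun(tibble::as_tibble(as.data.frame(big)))
    pm <- matrix(as.numeric(preds), nrow = nb)  # nb x (n_coal * m)
    v <- matrix(colMeans(pm), nrow = n_coal)    # coalition values per sample
    if (is.na(base)) base <- v[1, 1]
    vfull[idx] <- v[n_coal, seq_len(m)]
    for (j in seq_len(p)) {
      without <- which(!masks[, j])
      with_j <- without + bitwShiftL(1L, j - 1L)
      wgt <- wk[sizes[without] + 1]
      phi[idx, j] <- phi[idx, j] +
        as.numeric(crossprod(wgt, v[with_j, , drop = FALSE] -
                                   v[without, , drop = FALSE]))
    }
  }
  structure(list(values = phi, base_value = base, predictions = vfull,
                 target = if (inherits(model, "recovery_fit")) model$target
                          else NA_character_,
                 n_analysis = n, n_calibration = nrow(calibration),
                 n_background = nb),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("<shap_report> target: %s, %d samples x %d features\n",
              x$target, x$n_analysis, ncol(x$values)))
  print(tidy(x), n = ncol(x$values))
  invisible(x)
}

#' @describeIn shap_values Mean absolute attribution per feature, ranked
#'   from most to least important.
#' @param x A `shap_report`.
#' @param ... Unused.
#' @export
tidy.shap_report <- function(x, ...) {
  out <- tibble::tibble(
    feature = colnames(x$values),
    mean_abs_shap = colMeans(abs(x$values))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_abs_shap))
  out$rank <- seq_len(nrow(out))
  out
}
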