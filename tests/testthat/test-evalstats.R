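test_that("predicted-versus-true regression recovers exact relations", {
  d <- tibble::tibble(true = seq(1, 10), est = seq(1, 10))
  # exact fits make lm warn about perfect residuals; that is the point here
  t1 <- suppressWarnings(tidy(regress_pred_vs_true(d, "est", "true")))
  expect_equal(t1$estimate, 1)
  expect_equal(t1$r.squared, 1)
  d$est2 <- 2 * d$true
  t2 <- suppressWarnings(tidy(regress_pred_vs_true(d, "est2", "true")))
  expect_equal(t2$estimate, 2)
  expect_equal(t2$r.squared, 1)
})

test_that("regression matches the closed-form OLS solution on a fixture", {
  x <- c(0.5, 1.2, 2.3, 2.9, 4.1, 5.0, 6.2, 7.7, 8.4, 9.9)
  y <- c(1.1, 1.9, 3.2, 3.1, 4.8, 6.1, 6.0, 8.2, 8.9, 10.4)
  d <- tibble::tibble(x = x, y = y)
  t <- tidy(regress_pred_vs_true(d, "y", "x"))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - (mean(y) - beta * mean(x)) - beta * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(t$estimate, beta, tolerance = 1e-10)
  expect_equal(t$r.squared, r2, tolerance = 1e-10)
  expect_identical(t$n, 10L)
  # orientation matters: swapping roles rescales the slope by R^2
  t_swap <- tidy(regress_pred_vs_true(d, "x", "y"))
  expect_equal(t_swap$estimate, r2 / beta, tolerance = 1e-10)
})

test_that("zero-variance truth is a degenerate regression", {
  d <- tibble::tibble(true = rep(3, 10), est = rnorm(10))
  expect_error(regress_pred_vs_true(d, "est", "true"), "degenerate")
})

test_that("Scott bandwidths follow sd * n^(-1/(d+4))", {
  x <- rnorm(1000)
  x <- (x - mean(x)) / sd(x) * 2  # sd exactly 2
  expect_equal(scott_bandwidth(x), 2 * 1000^(-0.2), tolerance = 1e-12)
  expect_equal(scott_bandwidth(x, d = 2), 2 * 1000^(-1 / 6),
               tolerance = 1e-12)
})

test_that("the univariate KDE integrates to one", {
  set.seed(51)
  k <- kde_scott(rnorm(2000))
  mass <- sum(k$density) * diff(k$x[1:2])
  expect_equal(mass, 1, tolerance = 0.01)
  expect_error(kde_scott(rep(1, 100)), "degenerate")
})

test_that("the 95% contour of a bivariate normal contains ~95% of points", {
  set.seed(52)
  x <- rnorm(2000)
  y <- rnorm(2000)
  k <- kde2d_scott(x, y)
  lev <- kde_contour_level(k, x, y, prob = 0.95)
  xf <- rnorm(2000)
  yf <- rnorm(2000)
  inside <- westvq:::interp_grid(k$x, k$y, k$z, xf, yf) >= lev
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
})

# a transparent stand-in model: a plain linear prediction function
linear_model <- function(coefs, intercept = 0) {
  function(newdata) {
    as.numeric(as.matrix(newdata[names(coefs)]) %*% coefs + intercept)
  }
}

test_that("Shapley attributions vanish for ignored features", {
  feats <- c("a", "b", "c", "d", "e")
  set.seed(53)
  pool <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(500 * 5),
                                                          500)), feats))
  model <- linear_model(c(a = 2, b = -1, c = 0.5, d = 0, e = 0))
  rep <- shap_values(model, pool[1:20, ], pool[21:500, ], features = feats,
                     n_background = 25)
  expect_lt(max(abs(rep$values[, "d"])), 1e-10)
  expect_lt(max(abs(rep$values[, "e"])), 1e-10)
})

test_that("linear-model attributions match the closed form and add up", {
  feats <- c("a", "b", "c", "d", "e", "f")
  set.seed(54)
  pool <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(400 * 6),
                                                          400)), feats))
  beta <- c(a = 1.5, b = -2, c = 0.3, d = 4, e = -0.7, f = 1)
  model <- linear_model(beta, intercept = 3)
  analysis <- pool[1:15, ]
  calibration <- pool[16:400, ]
  rep <- shap_values(model, analysis, calibration, features = feats,
                     n_background = 30)
  # for a linear model, phi_j = beta_j * (x_j - mean of background x_j);
  # recover the background actually used from the base value
  bg_contrib <- rep$base_value - 3
  closed <- sweep(as.matrix(analysis), 2, 0) %*% diag(beta)
  # additivity is exact for exact Shapley enumeration
  expect_equal(rowSums(rep$values), rep$predictions - rep$base_value,
               tolerance = 1e-10)
  # each attribution differs from beta_j * x_j by a sample-independent
  # background offset
  for (j in seq_along(feats)) {
    offs <- rep$values[, j] - closed[, j]
    expect_lt(diff(range(offs)), 1e-10)
  }
  # and the offsets total the background contribution
  expect_equal(sum(rep$values[1, ] - closed[1, ]), -bg_contrib,
               tolerance = 1e-10)
})

test_that("overlapping calibration and analysis subsets are rejected", {
  feats <- c("a", "b")
  pool <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  model <- linear_model(c(a = 1, b = 1))
  expect_error(
    shap_values(model, pool[1:10, ], pool[5:50, ], features = feats),
    "mutually exclusive")
})
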