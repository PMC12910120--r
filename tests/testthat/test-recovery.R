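test_that("parameter counts follow the dense-layer arithmetic", {
  expect_identical(count_params(mlp_spec()), 84097L)
  expect_identical(count_params(mlp_spec(hidden = integer(0))), 11L)
  expect_identical(count_params(mlp_spec(hidden = 64L)),
                   (10L * 64L + 64L) + (64L + 1L))
})

# small synthetic regression problem reused below: a smooth function of
# five features plus irrelevant ones
make_toy <- function(n, seed) {
  set.seed(seed)
  d <- tibble::tibble(
    fio2 = runif(n, 0.2, 1), vco2 = runif(n, 100, 450),
    rq = runif(n, 0.7, 1), qt = runif(n, 4, 8),
    pa_n2 = runif(n, 100, 600), hb = runif(n, 3, 21),
    ph = runif(n, 6.9, 7.7), pa_o2 = runif(n, 40, 500),
    pa_co2 = runif(n, 15, 90), sa_o2 = runif(n, 0.6, 1)
  )
  d$y <- 30 * d$fio2 + 0.05 * d$pa_n2 - 10 * d$rq + rnorm(n, sd = 0.1)
  d
}

test_that("a constant target collapses to that constant", {
  d <- make_toy(400, 31)
  d$y <- 5
  set.seed(32)
  # full-batch, large-epsilon, decayed RMSprop: near-zero gradients then
  # step proportionally, so the degenerate fit converges all the way down
  fit <- fit_recovery(d, "y", mlp_spec(hidden = 8L, epochs = 4000,
                                       batch_size = 400,
                                       learning_rate = 0.1, epsilon = 0.1,
                                       decay = 0.002,
                                       validation_split = 0,
                                       patience = 10000))
  p <- predict(fit, d[1:50, ])
  expect_true(all(abs(p - 5) < 1e-3))
})

test_that("permuted labels carry no recoverable signal", {
  d <- make_toy(2000, 33)
  set.seed(34)
  d$y <- sample(d$y)
  train <- d[1:1500, ]
  test <- d[1501:2000, ]
  set.seed(35)
  fit <- fit_recovery(train, "y", mlp_spec(hidden = c(32L, 32L),
                                           epochs = 15, batch_size = 128))
  p <- predict(fit, test)
  r2 <- summary(lm(p ~ test$y))$r.squared
  expect_lt(r2, 0.1)
})

test_that("training learns a smooth target and is seed-deterministic", {
  d <- make_toy(3000, 36)
  set.seed(37)
  fit1 <- fit_recovery(d, "y", mlp_spec(hidden = c(32L, 32L), epochs = 60,
                                        batch_size = 64))
  set.seed(37)
  fit2 <- fit_recovery(d, "y", mlp_spec(hidden = c(32L, 32L), epochs = 60,
                                        batch_size = 64))
  expect_identical(fit1$weights, fit2$weights)
  fresh <- make_toy(500, 38)
  p <- predict(fit1, fresh)
  expect_gt(summary(lm(p ~ fresh$y))$r.squared, 0.98)
})

test_that("batch prediction equals row-by-row prediction", {
  d <- make_toy(200, 39)
  set.seed(40)
  fit <- fit_recovery(d, "y", mlp_spec(hidden = 16L, epochs = 3,
                                       batch_size = 64))
  batch <- predict(fit, d[1:20, ])
  single <- vapply(1:20, function(i) as.numeric(predict(fit, d[i, ])),
                   numeric(1))
  expect_equal(as.numeric(batch), single, tolerance = 1e-12)
})

test_that("out-of-range predictions are flagged, never clipped", {
  d <- make_toy(300, 41)
  set.seed(42)
  fit <- fit_recovery(d, "y", mlp_spec(hidden = 16L, epochs = 3,
                                       batch_size = 64))
  # force an out-of-range network output through a synthetic final layer
  fit$weights <- list(matrix(0, 10, 1))
  fit$biases <- list(matrix(fit$target_range[2] + 25, 1, 1))
  p <- predict(fit, d[1:5, ])
  expect_true(all(p > fit$target_range[2]))  # value untouched
  expect_true(all(attr(p, "out_of_range")))
  aug <- augment(fit, d[1:5, ])
  expect_true(all(aug$.out_of_range))
})

test_that("missing feature columns raise a schema error", {
  d <- make_toy(200, 43)
  set.seed(44)
  fit <- fit_recovery(d, "y", mlp_spec(hidden = 8L, epochs = 2,
                                       batch_size = 64))
  expect_error(predict(fit, d[, -1]), "fio2")
  expect_error(fit_recovery(d[, -2], "y"), "vco2")
})
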