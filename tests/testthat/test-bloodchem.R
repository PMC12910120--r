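ctx0 <- blood_context(hb = 15, be = 0, p50 = 26.86)

test_that("saturation is 0.5 at the effective P50 and the curve inverts to it", {
  expect_equal(o2_saturation(26.86, 7.40, 40, ctx0), 0.5, tolerance = 0.005)
  # oracle: invert the curve numerically for S = 0.5 at standard conditions;
  # the root must equal the standard P50 input
  for (p50 in c(22, 26.86, 31)) {
    ctx <- blood_context(15, 0, p50)
    root <- uniroot(function(p) o2_saturation(p, 7.40, 40, ctx) - 0.5,
                    c(5, 80), tol = 1e-9)$root
    expect_equal(root, p50, tolerance = 1e-3)
  }
})

test_that("saturation is monotone, bounded, and right-shifts with P50", {
  po2 <- seq(1, 700, by = 1)
  s <- o2_saturation(po2, 7.40, 40, ctx0)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  expect_gt(o2_saturation(690, 7.40, 40, ctx0), 0.999)
  # higher standard P50 lowers saturation at any fixed PO2
  s_hi <- o2_saturation(po2, 7.40, 40, blood_context(15, 0, 33.7))
  expect_true(all(s_hi < s))
  # Bohr effect: acidosis lowers saturation
  expect_lt(o2_saturation(40, 7.20, 60, ctx0),
            o2_saturation(40, 7.40, 40, ctx0))
  expect_error(o2_saturation(-1, 7.4, 40, ctx0), "positive")
})

test_that("oxygen content is bound plus dissolved, linear in haemoglobin", {
  expect_equal(o2_content(100, 0.5, blood_context(hb = 0)), 0.003 * 100)
  c1 <- o2_content(100, 0.9, blood_context(hb = 7))
  c2 <- o2_content(100, 0.9, blood_context(hb = 14))
  expect_equal(c2 - 0.3, 2 * (c1 - 0.3), tolerance = 1e-12)
  # textbook arterial content at full saturation
  full <- o2_content(100, 1.0, blood_context(hb = 15))
  expect_gt(full, 19.5)
  expect_lt(full, 21.5)
  expect_error(o2_content(100, 1.4, ctx0), "so2")
})

test_that("CO2 content shows the Haldane effect and rises with PCO2", {
  expect_gt(co2_content(40, 7.40, 0, ctx0), co2_content(40, 7.40, 1, ctx0))
  pco2 <- seq(10, 200, by = 2)
  ph <- ph_from_pco2_be(pco2, ctx0)
  cc <- co2_content(pco2, ph, 0.9, ctx0)
  expect_true(all(diff(cc) > 0))
  # arterial point near the textbook 48 mL/dL
  art <- co2_content(40, 7.40, 0.97, ctx0)
  expect_gt(art, 46)
  expect_lt(art, 50)
  expect_error(co2_content(-5, 7.4, 0.9, ctx0), "positive")
})

test_that("Van Slyke pH inverts correctly and round-trips base excess", {
  expect_equal(ph_from_pco2_be(40, ctx0), 7.40, tolerance = 0.01)
  # acidaemia from negative base excess, against an independent bisection
  ctx_acid <- blood_context(15, -10)
  ph <- ph_from_pco2_be(40, ctx_acid)
  expect_gt(ph, 7.22)
  expect_lt(ph, 7.30)
  oracle <- uniroot(function(p) be_from_ph_pco2(p, 40, ctx_acid) + 10,
                    c(6.5, 8.2), tol = 1e-9)$root
  expect_equal(ph, oracle, tolerance = 1e-5)
  # pH strictly decreasing in PCO2
  ph_seq <- ph_from_pco2_be(seq(15, 120, by = 5), ctx0)
  expect_true(all(diff(ph_seq) < 0))
  # round trip over the full Table 1 context space
  set.seed(421)
  for (i in 1:50) {
    ctx <- blood_context(runif(1, 3, 21), runif(1, -25, 20))
    pco2 <- runif(1, 12, 150)
    be_back <- be_from_ph_pco2(ph_from_pco2_be(pco2, ctx), pco2, ctx)
    expect_lt(abs(be_back - ctx$be), 0.1)
  }
})

test_that("nitrogen content is exactly linear through the origin", {
  expect_identical(n2_content(0), 0)
  p <- c(5, 100, 573)
  expect_equal(n2_content(2 * p) / n2_content(p), rep(2, 3))
  expect_equal(n2_content(573), lung_constants()$alpha_n2 * 573)
  expect_error(n2_content(-1), "non-negative")
})

test_that("content functions are smooth (finite-difference continuity)", {
  h <- 1e-4
  for (p in c(20, 40, 90, 200)) {
    d1 <- (o2_saturation(p + h, 7.4, 40, ctx0) -
           o2_saturation(p - h, 7.4, 40, ctx0)) / (2 * h)
    d2 <- (o2_saturation(p + 2 * h, 7.4, 40, ctx0) -
           o2_saturation(p - 2 * h, 7.4, 40, ctx0)) / (4 * h)
    expect_equal(d1, d2, tolerance = 1e-4)
  }
})

test_that("blood_state and pressures_from_contents are mutual inverses", {
  st <- blood_state(85, 42, 560, ctx0)
  back <- pressures_from_contents(st$c_o2, st$c_co2, ctx0)
  expect_true(back$converged)
  expect_equal(back$po2, 85, tolerance = 1e-4)
  expect_equal(back$pco2, 42, tolerance = 1e-4)
})
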