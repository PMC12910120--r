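test_that("random draws stay inside their assigned ranges", {
  set.seed(10)
  d <- draw_case_inputs(1e5)
  spec <- sampling_spec()
  for (v in setdiff(names(spec), "log_scale")) {
    expect_gte(min(d[[v]]), spec[[v]][1])
    expect_lte(max(d[[v]]), spec[[v]][2])
  }
  # log-uniform meanV/Q: median at the geometric midpoint of the range
  expect_equal(median(d$meanvq), sqrt(0.3 * 3.0), tolerance = 0.012)
  # while linear variables centre on the arithmetic midpoint
  expect_equal(median(d$shunt), 25, tolerance = 0.02 * 50)
})

test_that("draws are deterministic under a fixed seed", {
  set.seed(123)
  a <- draw_case_inputs(100)
  set.seed(123)
  b <- draw_case_inputs(100)
  expect_identical(a, b)
})

test_that("training cohorts hit the requested count and pass their filter", {
  set.seed(21)
  coh <- generate_cohort(300, role = "train")
  expect_identical(nrow(coh), 300L)
  expect_true(all(passes_filters(coh, filter_spec("train"))))
  meta <- attr(coh, "cohort_meta")
  expect_gte(meta$n_drawn, 300)
  expect_identical(meta$n_stage1, 300)
})

test_that("test cohorts apply the reduced clinical ranges on top", {
  set.seed(22)
  coh <- generate_cohort(400, role = "test")
  expect_lt(nrow(coh), 400)
  expect_true(all(passes_filters(coh, filter_spec("train"))))
  expect_true(all(passes_filters(coh, filter_spec("test"))))
  expect_true(all(coh$ph <= 7.8))
  expect_true(all(coh$pa_o2 > 40))
  expect_true(all(coh$pa_co2 >= 10 & coh$pa_co2 <= 200))
  meta <- attr(coh, "cohort_meta")
  expect_identical(meta$n_final, nrow(coh))
})

test_that("extreme results concentrate at low FiO2 with high shunt", {
  set.seed(23)
  inputs <- draw_case_inputs(4000)
  solved <- solve_lung(inputs)
  rejected <- !passes_filters(solved, filter_spec("train"))
  hi <- solved$shunt > 25
  expect_lt(suppressWarnings(
    cor(solved$fio2[hi], as.numeric(rejected[hi]), method = "spearman")), 0)
})

test_that("cohorts round-trip through CSV with their metadata sidecar", {
  set.seed(24)
  coh <- generate_cohort(50, role = "train")
  path <- file.path(tempdir(), "cohort-test.csv")
  write_cohort(coh, path, seed = 24)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$pa_o2, coh$pa_o2, tolerance = 1e-6)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$seed, 24L)
  expect_identical(meta$constants$p_dry, 713L)
  unlink(c(path, paste0(path, ".json")))
})

test_that("parquet output round-trips when arrow is available", {
  skip_if_not_installed("arrow")
  set.seed(25)
  coh <- generate_cohort(30, role = "train")
  path <- file.path(tempdir(), "cohort-test.parquet")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$pa_n2, coh$pa_n2)
  unlink(c(path, paste0(path, ".json")))
})

test_that("the ten monitoring features are present in every cohort", {
  set.seed(26)
  coh <- generate_cohort(20, role = "train")
  expect_true(all(monitoring_features() %in% names(coh)))
  expect_identical(length(monitoring_features()), 10L)
})
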