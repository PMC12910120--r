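#' Sampling specification for randomized case inputs
#'
#' Ranges of the ten monitoring inputs. All variables are drawn uniformly
#' on a linear scale except `meanvq`, which is drawn log-uniformly (its
#' physiological range is multiplicative).
#'
#' @return A list of class `sampling_spec` with one `c(min, max)` range per
#'   variable and a `log_scale` character vector naming log-uniform ones.
#' @examples
#' sampling_spec()$shunt
#' @export
sampling_spec <- function() {
  structure(list(
    shunt = c(0, 50),        # % of pulmonary blood flow
    logsd = c(0.40, 2.0),
    meanvq = c(0.30, 3.0),   # log-uniform
    fio2 = c(0.20, 1.0),
    vco2 = c(100, 450),      # mL/min
    rq = c(0.7, 1.0),
    hb = c(3.0, 21.0),       # g/dL
    p50 = c(20.7, 33.7),     # mm Hg
    be = c(-25, 20),         # mEq/L
    qt = c(4.0, 8.0),        # L/min
    log_scale = "meanvq"
  ), class = "sampling_spec")
}

#' Inclusion filters for model-generated blood gases
#'
#' The training filter keeps cases with physiologically representable
#' outputs; the test filter additionally narrows pH, PaO2 and PaCO2 to
#' better emulate clinical scenarios.
#'
#' @param role `"train"` or `"test"`.
#' @return List of class `filter_spec` with named `c(min, max)` ranges
#'   (open bounds encoded as -Inf/Inf) and the role.
#' @export
filter_spec <- function(role = c("train", "test")) {
  role <- match.arg(role)
  base <- list(
    ph = c(6.8, 8.0),
    pa_o2 = c(0, Inf),    # strictly greater than 0
    pa_co2 = c(0, Inf),
    pv_o2 = c(0, Inf),
    pv_co2 = c(0, Inf),
    qva = c(-Inf, 90),    # strictly less than 90
    vd_alv = c(0, 90),
    va = c(1.5, 40)
  )
  extra <- if (role == "test") {
    list(ph = c(6.8, 7.8), pa_o2 = c(40, Inf), pa_co2 = c(10, 200))
  } else {
    list()
  }
  structure(c(modifyList(base, extra), list(role = role)),
            class = "filter_spec")
}

#' Draw randomized case inputs
#'
#' Independent uniform draws from the [sampling_spec()] ranges
#' (log-uniform for `meanvq`). Deterministic under a fixed R random seed.
#'
#' @param n Number of cases to draw.
#' @param spec A [sampling_spec()].
#' @return Tibble with columns `shunt`, `logsd`, `meanvq`, `fio2`, `vco2`,
#'   `rq`, `hb`, `be`, `p50`, `qt`.
#' @examples
#' set.seed(1)
#' draw_case_inputs(3)
#' @export
draw_case_inputs <- function(n, spec = sampling_spec()) {
  stopifnot(n >= 1)
  vars <- setdiff(names(spec), "log_scale")
  draws <- lapply(vars, function(v) {
    r <- spec[[v]]
    if (v %in% spec$log_scale) {
      exp(stats::runif(n, log(r[1]), log(r[2])))
    } else {
      stats::runif(n, r[1], r[2])
    }
  })
  tibble::as_tibble(setNames(draws, vars))[
    , c("shunt", "logsd", "meanvq", "fio2", "vco2", "rq", "hb", "be",
        "p50", "qt")]
}

#' The ten single-measurement monitoring features
#'
#' Feature columns used to train the recovery networks: FiO2, VCO2, R, QT,
#' PaN2, plus the five routine arterial blood gas measurements (Hb, pH,
#' PaO2, PaCO2, SaO2).
#'
#' @return Character vector of column names.
#' @export
monitoring_features <- function() {
  c("fio2", "vco2", "rq", "qt", "pa_n2", "hb", "ph", "pa_o2", "pa_co2",
    "sa_o2")
}

#' Apply an inclusion filter to solved cases
#'
#' @param solved Tibble from [solve_lung()].
#' @param filters A [filter_spec()].
#' @return Logical vector: TRUE where the row passes every range (rows
#'   with any required value missing, non-converged or infeasible fail).
#' @export
passes_filters <- function(solved, filters = filter_spec("train")) {
  stopifnot(inherits(filters, "filter_spec"))
  vars <- setdiff(names(filters), "role")
  keep <- solved$converged & solved$feasible
  keep[is.na(keep)] <- FALSE
  for (v in vars) {
    r <- filters[[v]]
    x <- solved[[v]]
    # interval-stated ranges are closed; "greater/less than" bounds strict
    lo_ok <- if (is.finite(r[1]) && v %in% c("ph", "vd_alv", "va", "pa_co2")) {
      x >= r[1]
    } else {
      x > r[1]
    }
    hi_ok <- if (v == "qva") x < r[2] else x <= r[2]
    keep <- keep & !is.na(x) & lo_ok & hi_ok
  }
  keep
}

#' Generate a simulated monitoring cohort
#'
#' Draws random inputs, solves each case with the multicompartment lung
#' model, and filters. In the `"train"` role, generation continues until
#' exactly `n` cases pass the training filters. In the `"test"` role,
#' generation continues until `n` cases pass the *training* filters, after
#' which the additional test restrictions are applied and only survivors
#' are returned (mirroring two-stage dataset construction).
#'
#' @param n Target number of stage-one accepted rows.
#' @param role `"train"` or `"test"`.
#' @param spec A [sampling_spec()].
#' @param config A [lung_config()].
#' @param chunk_size Cases drawn per solver batch.
#' @return Tibble of simulated cases (inputs + solved gases + profile).
#'   Attribute `cohort_meta` records counts: `n_drawn`, `n_infeasible`,
#'   `n_nonconverged`, `n_stage1`, `n_final`, plus the role.
#' @examples
#' \donttest{
#' set.seed(42)
#' cohort <- generate_cohort(200, role = "train")
#' nrow(cohort)
#' }
#' @export
generate_cohort <- function(n, role = c("train", "test"),
                            spec = sampling_spec(), config = lung_config(),
                            chunk_size = 5000) {
  role <- match.arg(role)
  train_f <- filter_spec("train")
  pieces <- list()
  n_acc <- 0L
  n_drawn <- 0L
  n_infeasible <- 0L
  n_nonconv <- 0L
  window_drawn <- 0L
  window_acc <- 0L
  while (n_acc < n) {
    m <- min(chunk_size, max(1000L, as.integer((n - n_acc) * 2)))
    inputs <- draw_case_inputs(m, spec)
    solved <- solve_lung(inputs, config)
    keep <- passes_filters(solved, train_f)
    n_drawn <- n_drawn + m
    n_infeasible <- n_infeasible + sum(!solved$feasible)
    n_nonconv <- n_nonconv + sum(solved$feasible & !solved$converged)
    window_drawn <- window_drawn + m
    window_acc <- window_acc + sum(keep)
    if (window_drawn >= 10000L) {
      if (window_acc / window_drawn < 0.01) {
        stop("acceptance rate below 1% over a 10,000-draw window: ",
             "check solver or filter configuration", call. = FALSE)
      }
      window_drawn <- 0L
      window_acc <- 0L
    }
    pieces[[length(pieces) + 1L]] <- solved[keep, , drop = FALSE]
    n_acc <- n_acc + sum(keep)
  }
  stage1 <- dplyr::bind_rows(pieces)
  stage1 <- stage1[seq_len(n), , drop = FALSE]
  out <- stage1
  if (role == "test") {
    out <- stage1[passes_filters(stage1, filter_spec("test")), ,
                  drop = FALSE]
  }
  attr(out, "cohort_meta") <- list(
    role = role, n_drawn = n_drawn, n_infeasible = n_infeasible,
    n_nonconverged = n_nonconv, n_stage1 = n, n_final = nrow(out)
  )
  out
}

#' Write / read a cohort with a metadata sidecar
#'
#' Writes the case table as CSV (or Parquet when the arrow package is
#' requested) plus a JSON sidecar carrying generation metadata and the
#' model constants for provenance.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param path Output file path (`.csv` or `.parquet`).
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  fmt <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
  if (fmt == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for parquet output", call. = FALSE)
    }
    arrow::write_parquet(cohort, path)
  } else {
    readr::write_csv(cohort, path)
  }
  meta <- attr(cohort, "cohort_meta")
  sidecar <- list(
    format = fmt, n_rows = nrow(cohort), columns = names(cohort),
    seed = seed, meta = meta, constants = lung_constants()
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for parquet input", call. = FALSE)
    }
    out <- tibble::as_tibble(arrow::read_parquet(path))
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "cohort_meta") <- jsonlite::read_json(sidecar)$meta
  }
  out
}

#' Simulate a single monitoring case
#'
#' Convenience wrapper: one set of inputs in, one solved case out.
#'
#' @inheritParams solve_lung_case
#' @param hb,be,p50 Blood context values.
#' @return One-row tibble as in [solve_lung()].
#' @examples
#' simulate_case(shunt = 20, logsd = 1, meanvq = 1, fio2 = 0.5)
#' @export
simulate_case <- function(shunt, logsd, meanvq, fio2, vco2 = 200, rq = 0.8,
                          hb = 15, be = 0, p50 = 26.86, qt = 5,
                          config = lung_config()) {
  solve_lung(tibble::tibble(shunt = shunt, logsd = logsd, meanvq = meanvq,
                            fio2 = fio2, vco2 = vco2, rq = rq, hb = hb,
                            be = be, p50 = p50, qt = qt), config)
}
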