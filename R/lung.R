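#' Solve whole-lung steady-state gas exchange for a table of cases
#'
#' For each row of `cases` the solver builds the compartment set, then
#' iterates the mixed-venous composition to the steady state in which (i)
#' the Fick principle links arterial and venous O2/CO2 contents through
#' VO2 = VCO2/R and VCO2, and (ii) whole-lung net nitrogen flux is zero
#' (the body neither produces nor consumes N2, so venous and arterial N2
#' contents are equal). Each compartment satisfies simultaneous
#' O2/CO2/N2 mass balances with expired-volume bookkeeping, alveolar
#' pressures summing to 713 mm Hg, and end-capillary blood equilibrated to
#' alveolar gas. The arterial point is the flow-weighted content mixture of
#' shunted mixed-venous blood and compartment end-capillary bloods.
#'
#' @param cases Data frame with columns `shunt`, `logsd`, `meanvq`, `fio2`,
#'   `vco2` (mL/min), `rq`, `hb` (g/dL), `be` (mEq/L), `p50` (mm Hg),
#'   `qt` (L/min). Extra columns are carried through.
#' @param config A [lung_config()].
#' @return The input tibble with solution columns appended: arterial
#'   (`pa_o2`, `pa_co2`, `pa_n2`, `ph`, `sa_o2`), mixed-venous (`pv_o2`,
#'   `pv_co2`, `pv_n2`), contents (`ca_o2`, `ca_co2`, `cv_o2`, `cv_co2`),
#'   respiratory profile (`qva` venous admixture %, `va` alveolar
#'   ventilation L/min, `mpaco2` ventilation-weighted mean alveolar PCO2,
#'   `vd_alv` alveolar dead-space %), plus `converged` and `feasible`
#'   flags. Rows whose Fick balance admits no venous state with positive
#'   O2 content are reported with `pv_o2 = 0` and `feasible = FALSE`.
#' @examples
#' cases <- tibble::tibble(shunt = 10, logsd = 0.8, meanvq = 1, fio2 = 0.21,
#'                         vco2 = 200, rq = 0.8, hb = 15, be = 0,
#'                         p50 = 26.86, qt = 5)
#' solve_lung(cases)
#' @export
solve_lung <- function(cases, config = lung_config()) {
  req <- c("shunt", "logsd", "meanvq", "fio2", "vco2", "rq", "hb", "be",
           "p50", "qt")
  missing_cols <- setdiff(req, names(cases))
  if (length(missing_cols) > 0) {
    stop("`cases` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sol <- cpp_solve_cases(as.data.frame(cases[req]), unclass(config))
  dplyr::bind_cols(tibble::as_tibble(cases), tibble::as_tibble(sol))
}

#' Solve a single case with per-compartment detail
#'
#' Like [solve_lung()] but for one case, returning the compartment-level
#' solution (alveolar pressures, per-compartment perfusion and expired
#' ventilation) needed for respiratory-profile and dead-space work.
#'
#' @inheritParams vq_compartments
#' @param fio2 Inspired O2 fraction.
#' @param vco2 CO2 production, mL/min.
#' @param rq Respiratory quotient (VCO2/VO2).
#' @param ctx A [blood_context()].
#' @param config A [lung_config()].
#' @param compartments Optional custom compartment set: a data frame with
#'   `ratio` and `q_frac` columns (e.g. a hand-built two-compartment lung);
#'   overrides the lognormal construction.
#' @return A list of class `lung_solution`: `summary` (one-row tibble as in
#'   [solve_lung()]) and `compartments` (tibble with `ratio`, `q_frac`,
#'   `q`, `ve`, `pa_o2`, `pa_co2`, `pa_n2`, `flux_o2`, `flux_co2`,
#'   `flux_n2` in mL/min).
#' @examples
#' sol <- solve_lung_case(shunt = 20, logsd = 1, meanvq = 1, fio2 = 0.5)
#' sol$summary$qva
#' @export
solve_lung_case <- function(shunt, logsd, meanvq, fio2, vco2 = 200,
                            rq = 0.8, qt = 5, ctx = blood_context(),
                            config = lung_config(), compartments = NULL) {
  if (is.null(compartments)) {
    r <- cpp_solve_lung_detail(shunt, logsd, meanvq, fio2, vco2, rq, qt,
                               ctx$hb, ctx$be, ctx$p50, unclass(config))
  } else {
    r <- cpp_solve_lung_detail(shunt, logsd, meanvq, fio2, vco2, rq, qt,
                               ctx$hb, ctx$be, ctx$p50, unclass(config),
                               compartments$ratio, compartments$q_frac)
  }
  if (!r$ok) {
    stop("lung solve failed (feasible = ", r$feasible, ", converged = ",
         r$converged, ") for shunt=", shunt, " logsd=", logsd,
         " meanvq=", meanvq, " fio2=", fio2, call. = FALSE)
  }
  qnb <- (1 - shunt / 100) * qt
  vblood <- blood_state(max(r$pv_o2, 1e-6), r$pv_co2, max(r$pv_n2, 0), ctx)
  comp <- tibble::tibble(
    ratio = r$ratio, q_frac = r$q_frac, q = r$q_frac * qnb,
    ve = r$ratio * r$q_frac * qnb,
    pa_o2 = r$comp_pao2, pa_co2 = r$comp_paco2,
    pa_n2 = pmax(r$comp_pan2, 0)
  )
  cc <- blood_state(comp$pa_o2, comp$pa_co2, comp$pa_n2, ctx)
  comp$flux_o2 <- 10 * comp$q * (cc$c_o2 - vblood$c_o2)
  comp$flux_co2 <- 10 * comp$q * (cc$c_co2 - vblood$c_co2)
  comp$flux_n2 <- 10 * comp$q * (cc$c_n2 - vblood$c_n2)
  summary <- tibble::tibble(
    shunt = shunt, logsd = logsd, meanvq = meanvq, fio2 = fio2,
    vco2 = vco2, rq = rq, hb = ctx$hb, be = ctx$be, p50 = ctx$p50, qt = qt,
    pa_o2 = r$pa_o2, pa_co2 = r$pa_co2, pa_n2 = r$pa_n2, ph = r$ph,
    sa_o2 = r$sa_o2, pv_o2 = r$pv_o2, pv_co2 = r$pv_co2, pv_n2 = r$pv_n2,
    ca_o2 = r$ca_o2, ca_co2 = r$ca_co2, cv_o2 = r$cv_o2, cv_co2 = r$cv_co2,
    qva = r$qva, va = r$va, mpaco2 = r$mpaco2, vd_alv = r$vd_alv,
    converged = r$converged, feasible = r$feasible, n_iter = r$n_iter
  )
  structure(list(summary = summary, compartments = comp,
                 ctx = ctx, config = config),
            class = "lung_solution")
}

#' @export
print.lung_solution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<lung_solution> %d compartments + shunt %.1f%%\n", nrow(x$compartments),
    s$shunt))
  cat(sprintf("  PaO2 %.1f  PaCO2 %.1f  PaN2 %.1f mm Hg  pH %.3f  SaO2 %.3f\n",
              s$pa_o2, s$pa_co2, s$pa_n2, s$ph, s$sa_o2))
  cat(sprintf("  Qva %.1f%%  VA %.2f L/min  mPACO2 %.1f  VDalv %.1f%%\n",
              s$qva, s$va, s$mpaco2, s$vd_alv))
  invisible(x)
}

#' @export
tidy.lung_solution <- function(x, ...) x$compartments

#' @export
glance.lung_solution <- function(x, ...) x$summary

#' Riley venous admixture from oxygen contents
#'
#' `Qva/Qt = (Cc'O2 - CaO2) / (Cc'O2 - CvO2) * 100`, the fraction of
#' cardiac output that would have to bypass an "ideal" compartment to
#' reproduce the arterial O2 content. Inside the solver the ideal
#' end-capillary content is computed at the ideal alveolar PO2 from the
#' alveolar gas equation with PACO2 equal to arterial PCO2.
#'
#' @param ca_o2 Arterial O2 content, mL/dL.
#' @param cv_o2 Mixed-venous O2 content, mL/dL.
#' @param cc_o2 Ideal end-capillary O2 content, mL/dL.
#' @return Venous admixture, % of cardiac output.
#' @examples
#' venous_admixture(ca_o2 = 19, cv_o2 = 15, cc_o2 = 20)
#' @export
venous_admixture <- function(ca_o2, cv_o2, cc_o2) {
  if (any(cc_o2 <= cv_o2)) {
    stop("undefined venous admixture: ideal end-capillary content must ",
         "exceed mixed-venous content", call. = FALSE)
  }
  100 * (cc_o2 - ca_o2) / (cc_o2 - cv_o2)
}

#' Respiratory profile of a solved lung
#'
#' Summation over the compartment set: total expired alveolar ventilation
#' `VA = sum(ve)`, ventilation-weighted mean alveolar PCO2
#' `mPACO2 = sum(ve * PACO2) / VA`, and the alveolar dead-space fraction
#' `100 * (PaCO2 - mPACO2) / PaCO2`, clipped at zero.
#'
#' @param solution A `lung_solution` from [solve_lung_case()].
#' @return One-row tibble with `va`, `mpaco2`, `vd_alv`.
#' @export
respiratory_profile <- function(solution) {
  stopifnot(inherits(solution, "lung_solution"))
  comp <- solution$compartments
  va <- sum(comp$ve)
  mpaco2 <- sum(comp$ve * comp$pa_co2) / va
  pa_co2 <- solution$summary$pa_co2
  tibble::tibble(va = va, mpaco2 = mpaco2,
                 vd_alv = max(0, 100 * (pa_co2 - mpaco2) / pa_co2))
}
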