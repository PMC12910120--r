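#' Physical and chemical constants of the gas-exchange model
#'
#' All constants are fixed at body temperature (37 degrees C) and sea-level
#' barometric pressure. They are returned as a named list so they can be
#' serialized alongside generated datasets for provenance.
#'
#' @return Named list:
#' \describe{
#'   \item{pb}{barometric pressure, mm Hg (760)}
#'   \item{ph2o}{saturated water vapour pressure at 37 C, mm Hg (47)}
#'   \item{p_dry}{`pb - ph2o` = 713 mm Hg; alveolar partial pressures of
#'     O2, CO2 and N2 always sum to this value}
#'   \item{temp}{temperature, degrees C (37)}
#'   \item{pi_co2}{inspired PCO2, mm Hg (0)}
#'   \item{o2_capacity}{mL O2 bound per g haemoglobin (1.39)}
#'   \item{o2_solubility}{dissolved O2, mL/dL/mm Hg (0.003)}
#'   \item{alpha_n2}{N2 solubility in whole blood, mL/dL/mm Hg (0.0014).
#'     Only relative N2 fluxes matter for the zero-balance constraint, so
#'     any positive value yields the same arterial PN2.}
#'   \item{p50_reference}{P50 of the standard dissociation curve, mm Hg
#'     (26.86)}
#' }
#' @examples
#' lung_constants()$p_dry
#' @export
lung_constants <- function() {
  list(
    pb = 760, ph2o = 47, p_dry = 713, temp = 37, pi_co2 = 0,
    o2_capacity = 1.39, o2_solubility = 0.003, alpha_n2 = 0.0014,
    p50_reference = 26.86
  )
}

#' Solver configuration for the multicompartment lung model
#'
#' The lung comprises one shunt compartment (V/Q = 0) plus
#' `n_compartments` gas-exchanging compartments with V/Q ratios log-spaced
#' between `ratio_min` and `ratio_max` (70 compartments in total by
#' default). The whole-lung steady state is found by successive
#' substitution on the mixed-venous composition with the given damping
#' factor; convergence requires the proposed update to fall below the three
#' tolerances simultaneously.
#'
#' @param n_compartments Number of gas-exchanging compartments (default 69,
#'   i.e. 70 including the shunt compartment).
#' @param ratio_min,ratio_max Bounds of the fixed logarithmic V/Q grid.
#' @param damping Successive-substitution damping factor on the mixed-venous
#'   update.
#' @param max_iter Maximum venous-loop iterations before a case is declared
#'   non-convergent.
#' @param tol_cv_o2,tol_cv_co2 Convergence tolerance on mixed-venous O2 and
#'   CO2 content updates (mL/dL).
#' @param tol_pv_n2 Convergence tolerance on the mixed-venous PN2 update
#'   (mm Hg).
#' @return Named list of class `lung_config`.
#' @examples
#' lung_config()
#' @export
lung_config <- function(n_compartments = 69, ratio_min = 0.005,
                        ratio_max = 100, damping = 0.5, max_iter = 400,
                        tol_cv_o2 = 0.002, tol_cv_co2 = 0.002,
                        tol_pv_n2 = 0.02) {
  stopifnot(n_compartments >= 2, ratio_min > 0, ratio_max > ratio_min,
            damping > 0, damping <= 1, max_iter >= 1)
  structure(
    list(n_compartments = as.integer(n_compartments), ratio_min = ratio_min,
         ratio_max = ratio_max, damping = damping,
         max_iter = as.integer(max_iter), tol_cv_o2 = tol_cv_o2,
         tol_cv_co2 = tol_cv_co2, tol_pv_n2 = tol_pv_n2),
    class = "lung_config"
  )
}
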