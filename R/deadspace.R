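#' Forward-model mean alveolar PCO2 from recovered parameters
#'
#' Runs the lung model forward with the recovered distribution parameters
#' (shunt, logSD, mean V/Q) and the measured remainder of the case inputs,
#' returning the model's alveolar ventilation and ventilation-weighted
#' mean alveolar PCO2. Because arterial nitrogen transfer only involves
#' perfused, ventilated alveoli, this forward estimate is insensitive to
#' ventilation of non-perfused (Zone 1) lung, unlike capnometric
#' measurement.
#'
#' @param recovered Data frame with columns `shunt`, `logsd`, `meanvq`
#'   (e.g. network predictions).
#' @param measured Data frame (same height or height one) with the
#'   remaining case inputs: `fio2`, `vco2`, `rq`, `hb`, `be`, `p50`, `qt`.
#' @param config A [lung_config()].
#' @return Tibble with `va_model` (L/min), `mpaco2_model` (mm Hg) and a
#'   `converged` flag per row.
#' @examples
#' rec <- tibble::tibble(shunt = 15, logsd = 1, meanvq = 1)
#' mea <- tibble::tibble(fio2 = 0.4, vco2 = 200, rq = 0.8, hb = 14,
#'                       be = 0, p50 = 26.86, qt = 5)
#' forward_mpaco2(rec, mea)
#' @export
forward_mpaco2 <- function(recovered, measured, config = lung_config()) {
  n <- max(nrow(recovered), nrow(measured))
  cases <- dplyr::bind_cols(
    tibble::as_tibble(recovered[rep_len(seq_len(nrow(recovered)), n),
                                c("shunt", "logsd", "meanvq")]),
    tibble::as_tibble(measured[rep_len(seq_len(nrow(measured)), n),
                               c("fio2", "vco2", "rq", "hb", "be", "p50",
                                 "qt")])
  )
  sol <- solve_lung(cases, config)
  tibble::tibble(va_model = sol$va, mpaco2_model = sol$mpaco2,
                 converged = sol$converged & sol$feasible)
}

#' Estimate "true" (Zone 1) alveolar dead-space ventilation by dilution
#'
#' Ventilation of non-perfused alveoli (V/Q = infinity) carries inspired
#' gas with zero CO2, so it dilutes the expired alveolar CO2 signal
#' without touching arterial gases. With inspired PCO2 = 0 the CO2 mass
#' balance gives the extra expired volume needed to dilute the
#' model-derived mean alveolar PCO2 down to the capnometry-measured value:
#' `vdz1 = va_model * (mpaco2_model - mpaco2_meas) / mpaco2_meas`.
#'
#' @param va_model Model alveolar ventilation (perfused compartments),
#'   L/min.
#' @param mpaco2_model Forward-model mean alveolar PCO2, mm Hg.
#' @param mpaco2_meas Measured (volumetric capnometry) mean alveolar PCO2,
#'   mm Hg (> 0).
#' @return Tibble with `vdz1` (L/min), `vdz1_frac`
#'   (`vdz1 / (va_model + vdz1)`), and `clipped` (TRUE where a negative
#'   raw estimate — measurement noise — was reported as 0).
#' @examples
#' estimate_vdz1(va_model = 5, mpaco2_model = 40, mpaco2_meas = 32)
#' @export
estimate_vdz1 <- function(va_model, mpaco2_model, mpaco2_meas) {
  if (any(mpaco2_meas <= 0)) {
    stop("`mpaco2_meas` must be positive", call. = FALSE)
  }
  raw <- va_model * (mpaco2_model - mpaco2_meas) / mpaco2_meas
  clipped <- raw < 0
  vdz1 <- pmax(raw, 0)
  tibble::tibble(va_model = va_model, mpaco2_model = mpaco2_model,
                 mpaco2_meas = mpaco2_meas, vdz1 = vdz1,
                 vdz1_frac = vdz1 / (va_model + vdz1), clipped = clipped)
}

#' Dilute a solved case with injected Zone 1 ventilation
#'
#' Utility for validation: adds a non-perfused compartment carrying
#' ventilation `v_z` to a solved case and returns the mean alveolar PCO2 a
#' volume capnometer would see, `va * mpaco2 / (va + v_z)`.
#'
#' @param va Perfused-compartment alveolar ventilation, L/min.
#' @param mpaco2 Model mean alveolar PCO2, mm Hg.
#' @param v_z Injected Zone 1 ventilation, L/min.
#' @return Measured-style mean alveolar PCO2, mm Hg.
#' @export
dilute_mpaco2 <- function(va, mpaco2, v_z) {
  stopifnot(all(v_z >= 0))
  va * mpaco2 / (va + v_z)
}
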