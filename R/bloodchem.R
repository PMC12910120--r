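#' Blood context: fixed haematological and acid-base properties
#'
#' Bundles the per-case blood properties that the gas-exchange chemistry
#' depends on: haemoglobin concentration, base excess and standard P50.
#' Temperature and barometric pressure are fixed model constants (see
#' [lung_constants()]).
#'
#' @param hb Haemoglobin concentration, g/dL (3-21).
#' @param be Base excess, mEq/L (-25 to +20).
#' @param p50 Standard P50, mm Hg: the PO2 at 50% saturation under standard
#'   conditions (pH 7.40, PCO2 40 mm Hg); 20.7-33.7.
#' @return A list of class `blood_context`.
#' @examples
#' blood_context(hb = 15, be = 0)
#' @export
blood_context <- function(hb = 15, be = 0, p50 = 26.86) {
  stopifnot(is.numeric(hb), is.numeric(be), is.numeric(p50))
  if (any(hb < 0)) stop("`hb` must be non-negative", call. = FALSE)
  if (any(p50 <= 0)) stop("`p50` must be positive", call. = FALSE)
  structure(list(hb = hb, be = be, p50 = p50), class = "blood_context")
}

#' @export
print.blood_context <- function(x, ...) {
  cat(sprintf("<blood_context> Hb %.1f g/dL, BE %+.1f mEq/L, P50 %.2f mm Hg\n",
              x$hb[1], x$be[1], x$p50[1]))
  invisible(x)
}

#' Haemoglobin-oxygen saturation
#'
#' Standard oxyhaemoglobin dissociation curve (Severinghaus form,
#' `S = (x^3 + 150x) / (x^3 + 150x + 23400)`) evaluated at PO2 rescaled by
#' the effective in-vivo P50. The effective P50 applies the Bohr shift from
#' standard conditions (pH 7.40, PCO2 40 mm Hg) to the actual pH and PCO2
#' (`dlog10 P50 = -0.48 dpH + 0.06 dlog10 PCO2`) on top of the standard-P50
#' rescaling of the whole curve.
#'
#' @param po2 Oxygen partial pressure, mm Hg (> 0).
#' @param ph Blood pH.
#' @param pco2 CO2 partial pressure, mm Hg.
#' @param ctx A [blood_context()].
#' @return Saturation as a fraction in (0, 1). Vectorized over `po2`, `ph`
#'   and `pco2`.
#' @examples
#' o2_saturation(100, 7.40, 40, blood_context())
#' @export
o2_saturation <- function(po2, ph, pco2, ctx = blood_context()) {
  if (any(po2 <= 0)) stop("`po2` must be positive", call. = FALSE)
  n <- max(length(po2), length(ph), length(pco2))
  cpp_o2_sat(rep_len(po2, n), rep_len(ph, n), rep_len(pco2, n),
             rep_len(ctx$p50, n))
}

#' Oxygen content of whole blood
#'
#' Haemoglobin-bound plus dissolved oxygen:
#' `1.39 * hb * so2 + 0.003 * po2` (mL/dL).
#'
#' @param po2 Oxygen partial pressure, mm Hg.
#' @param so2 Haemoglobin-oxygen saturation, fraction in \[0, 1\].
#' @inheritParams o2_saturation
#' @return O2 content, mL/dL.
#' @examples
#' o2_content(100, 0.97, blood_context(hb = 15))
#' @export
o2_content <- function(po2, so2, ctx = blood_context()) {
  if (any(so2 < 0 | so2 > 1)) stop("`so2` must lie in [0, 1]", call. = FALSE)
  k <- lung_constants()
  k$o2_capacity * ctx$hb * so2 + k$o2_solubility * po2
}

#' Carbon dioxide content of whole blood
#'
#' Whole-blood CO2 content (Douglas relation): plasma content from the
#' Henderson-Hasselbalch equation with a pH-dependent apparent pK', scaled
#' to whole blood by a haemoglobin- and saturation-dependent factor that
#' carries the Haldane effect (content falls as saturation rises at fixed
#' PCO2).
#'
#' @inheritParams o2_content
#' @return CO2 content, mL/dL.
#' @examples
#' co2_content(40, 7.40, 0.97, blood_context(hb = 15))
#' @export
co2_content <- function(pco2, ph, so2, ctx = blood_context()) {
  if (any(pco2 <= 0)) stop("`pco2` must be positive", call. = FALSE)
  n <- max(length(pco2), length(ph), length(so2))
  cpp_co2_content(rep_len(pco2, n), rep_len(ph, n), rep_len(so2, n),
                  rep_len(ctx$hb, n))
}

#' pH from PCO2 and base excess (Van Slyke relation)
#'
#' Solves the Siggaard-Andersen Van Slyke equation
#' `BE = (1 - 0.0143 Hb) * ((HCO3 - 24.4) + (1.63 Hb + 9.5) (pH - 7.40))`
#' (with `HCO3 = 0.0307 PCO2 10^(pH - 6.1)`) for pH. At zero base excess
#' and PCO2 40 mm Hg the root is pH 7.40.
#'
#' @inheritParams o2_saturation
#' @return Blood pH. Vectorized over `pco2`.
#' @examples
#' ph_from_pco2_be(40, blood_context(be = 0))
#' @export
ph_from_pco2_be <- function(pco2, ctx = blood_context()) {
  if (any(pco2 <= 0)) stop("`pco2` must be positive", call. = FALSE)
  n <- length(pco2)
  ph <- cpp_ph_from_pco2_be(pco2, rep_len(ctx$hb, n), rep_len(ctx$be, n))
  if (any(ph < 6.5 | ph > 8.2)) {
    warning("pH outside [6.5, 8.2]: Van Slyke relation extrapolated",
            call. = FALSE)
  }
  ph
}

#' Base excess from pH and PCO2
#'
#' Direct evaluation of the same Van Slyke relation that
#' [ph_from_pco2_be()] inverts; useful for round-trip checks.
#'
#' @inheritParams o2_saturation
#' @return Base excess, mEq/L.
#' @export
be_from_ph_pco2 <- function(ph, pco2, ctx = blood_context()) {
  hco3 <- 0.0307 * pco2 * 10^(ph - 6.1)
  (1 - 0.0143 * ctx$hb) * ((hco3 - 24.4) + (1.63 * ctx$hb + 9.5) * (ph - 7.40))
}

#' Dissolved nitrogen content
#'
#' `alpha_N2 * pn2`, exactly linear through the origin.
#'
#' @param pn2 Nitrogen partial pressure, mm Hg (>= 0).
#' @return N2 content, mL/dL.
#' @examples
#' n2_content(573)
#' @export
n2_content <- function(pn2) {
  if (any(pn2 < 0)) stop("`pn2` must be non-negative", call. = FALSE)
  lung_constants()$alpha_n2 * pn2
}

#' Full blood state from partial pressures
#'
#' Completes a blood sample: derives pH from PCO2 and base excess,
#' saturation from the dissociation curve, and the three gas contents.
#'
#' @param po2,pco2,pn2 Partial pressures, mm Hg.
#' @inheritParams o2_saturation
#' @return A tibble with columns `po2`, `pco2`, `pn2`, `ph`, `so2`, `c_o2`,
#'   `c_co2`, `c_n2` (contents in mL/dL).
#' @examples
#' blood_state(po2 = 100, pco2 = 40, pn2 = 573)
#' @export
blood_state <- function(po2, pco2, pn2 = 0, ctx = blood_context()) {
  if (any(po2 <= 0)) stop("`po2` must be positive", call. = FALSE)
  if (any(pco2 <= 0)) stop("`pco2` must be positive", call. = FALSE)
  if (any(pn2 < 0)) stop("`pn2` must be non-negative", call. = FALSE)
  n <- max(length(po2), length(pco2), length(pn2))
  r <- cpp_blood_from_pressures(rep_len(po2, n), rep_len(pco2, n),
                                rep_len(pn2, n), rep_len(ctx$hb, n),
                                rep_len(ctx$be, n), rep_len(ctx$p50, n))
  tibble::tibble(po2 = rep_len(po2, n), pco2 = rep_len(pco2, n),
                 pn2 = rep_len(pn2, n), ph = r$ph, so2 = r$so2,
                 c_o2 = r$c_o2, c_co2 = r$c_co2, c_n2 = r$c_n2)
}

#' Partial pressures from gas contents
#'
#' Inverts the content relations: finds the (PO2, PCO2) pair whose blood
#' state reproduces the given O2 and CO2 contents at the blood context.
#' Used to recover arterial and mixed-venous gas pressures from
#' flow-weighted content mixtures.
#'
#' @param c_o2,c_co2 O2 and CO2 contents, mL/dL.
#' @inheritParams o2_saturation
#' @return A one-row tibble with `po2`, `pco2` and a logical `converged`.
#' @export
pressures_from_contents <- function(c_o2, c_co2, ctx = blood_context()) {
  r <- cpp_pressures_from_contents(c_o2, c_co2, ctx$hb, ctx$be, ctx$p50)
  tibble::tibble(po2 = r$po2, pco2 = r$pco2, converged = r$ok)
}
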