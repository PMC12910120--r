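#' Discretize a lognormal V/Q distribution onto the compartment grid
#'
#' Builds the compartment set of the West-type lung: a shunt fraction
#' (V/Q = 0) plus gas-exchanging compartments whose V/Q ratios sit on a
#' fixed logarithmic grid. Perfusion fractions are proportional to a
#' lognormal density in ln(V/Q), renormalized over the grid. `meanvq` is
#' the perfusion-weighted *arithmetic* mean unit V/Q ratio (the MIGET
#' first-moment convention), so the lognormal location parameter is
#' `ln(meanvq) - logsd^2 / 2`; `logsd` is the perfusion-weighted standard
#' deviation of ln(V/Q). Ventilation is *expired* alveolar ventilation, so
#' each compartment's ventilation is
#' `ratio * q_frac * (1 - shunt/100) * qt`.
#'
#' @param shunt Shunt, % of cardiac output perfusing unventilated units.
#' @param logsd Standard deviation of ln(V/Q) across perfusion.
#' @param meanvq Perfusion-weighted geometric mean V/Q ratio.
#' @param qt Cardiac output, L/min.
#' @param config A [lung_config()] giving grid size and bounds.
#' @return A tibble of class `vq_compartments` with one row per
#'   gas-exchanging compartment: `ratio`, `q_frac` (fraction of non-shunt
#'   flow), `q` (L/min), `ve` (expired alveolar ventilation, L/min).
#'   Attributes `shunt_frac` and `qt` carry the shunt compartment.
#' @examples
#' comp <- vq_compartments(shunt = 10, logsd = 0.8, meanvq = 1.0, qt = 5)
#' sum(comp$q_frac)
#' @export
vq_compartments <- function(shunt, logsd, meanvq, qt,
                            config = lung_config()) {
  stopifnot(shunt >= 0, shunt < 100, logsd > 0, meanvq > 0, qt > 0)
  lr <- seq(log(config$ratio_min), log(config$ratio_max),
            length.out = config$n_compartments)
  z <- (lr - (log(meanvq) - logsd^2 / 2)) / logsd
  w <- exp(-0.5 * z^2)
  if (sum(w) <= 0) {
    stop("degenerate V/Q distribution: no density on the compartment grid",
         call. = FALSE)
  }
  w <- w / sum(w)
  qnb <- (1 - shunt / 100) * qt
  out <- tibble::tibble(
    ratio = exp(lr),
    q_frac = w,
    q = w * qnb,
    ve = exp(lr) * w * qnb
  )
  structure(out, shunt_frac = shunt / 100, qt = qt,
            class = c("vq_compartments", class(out)))
}
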