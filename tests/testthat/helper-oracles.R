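# Independent oracles used across test files.  These deliberately solve the
# same steady-state equations by brute force (grid refinement) through the
# R-level blood chemistry API, independent of the compiled Newton path.

btps_to_stpd <- (273.15 / 310.15) * (713 / 760)
mmhg_to_ml <- 713 / (1000 * btps_to_stpd)

# residuals of the per-compartment mass balances for unit expired
# ventilation, computed entirely in R
compartment_residuals <- function(pao2, paco2, ratio, fio2, venous, ctx) {
  pan2 <- 713 - pao2 - paco2
  ph <- ph_from_pco2_be(paco2, ctx)
  so2 <- o2_saturation(pao2, ph, paco2, ctx)
  cc_o2 <- o2_content(pao2, so2, ctx)
  cc_co2 <- co2_content(paco2, ph, so2, ctx)
  cc_n2 <- n2_content(max(pan2, 0))
  q10 <- 10 / ratio
  u_o2 <- q10 * (cc_o2 - venous$c_o2)
  u_co2 <- q10 * (cc_co2 - venous$c_co2)
  u_n2 <- q10 * (cc_n2 - venous$c_n2)
  vi <- 1 + (u_o2 + u_co2 + u_n2) / (1000 * btps_to_stpd)
  c(vi * fio2 * 713 - pao2 - mmhg_to_ml * u_o2,
    -paco2 - mmhg_to_ml * u_co2)
}

# brute-force compartment solution: iterated 2-D grid refinement
oracle_compartment <- function(ratio, fio2, venous, ctx,
                               po2_range = c(1, 700),
                               pco2_range = c(1, 120), levels = 6,
                               n_grid = 31) {
  lo <- c(po2_range[1], pco2_range[1])
  hi <- c(po2_range[2], pco2_range[2])
  best <- c(NA, NA)
  for (lev in seq_len(levels)) {
    po2s <- seq(lo[1], hi[1], length.out = n_grid)
    pco2s <- seq(lo[2], hi[2], length.out = n_grid)
    score <- outer(po2s, pco2s, Vectorize(function(p, q) {
      if (p + q > 712.9) return(Inf)
      sum(abs(compartment_residuals(p, q, ratio, fio2, venous, ctx)))
    }))
    ij <- which(score == min(score), arr.ind = TRUE)[1, ]
    best <- c(po2s[ij[1]], pco2s[ij[2]])
    span <- (hi - lo) / (n_grid - 1)
    lo <- pmax(c(po2_range[1], pco2_range[1]), best - 2 * span)
    hi <- pmin(c(po2_range[2], pco2_range[2]), best + 2 * span)
  }
  list(pao2 = best[1], paco2 = best[2])
}

# independent whole-lung fixed point for a hand-built compartment set,
# using the grid-search compartment oracle throughout
oracle_lung <- function(ratios, q_frac, shunt, fio2, vco2, rq, qt, ctx,
                        n_iter = 80) {
  q_frac <- q_frac / sum(q_frac)
  sh <- shunt / 100
  vo2 <- vco2 / rq
  pv <- list(po2 = 40, pco2 = 46, pn2 = (1 - fio2) * 713)
  venous <- as.list(blood_state(pv$po2, pv$pco2, pv$pn2, ctx))
  for (it in seq_len(n_iter)) {
    cc <- lapply(seq_along(ratios), function(i) {
      s <- oracle_compartment(ratios[i], fio2, venous, ctx)
      st <- blood_state(s$pao2, s$paco2, max(713 - s$pao2 - s$paco2, 0), ctx)
      as.list(st)
    })
    ca_o2 <- sh * venous$c_o2 + (1 - sh) * sum(q_frac *
                                               sapply(cc, `[[`, "c_o2"))
    ca_co2 <- sh * venous$c_co2 + (1 - sh) * sum(q_frac *
                                                 sapply(cc, `[[`, "c_co2"))
    ca_n2 <- sh * venous$c_n2 + (1 - sh) * sum(q_frac *
                                               sapply(cc, `[[`, "c_n2"))
    cv_o2_t <- ca_o2 - vo2 / (10 * qt)
    cv_co2_t <- ca_co2 + vco2 / (10 * qt)
    pv_n2_t <- ca_n2 / lung_constants()$alpha_n2
    d <- c(cv_o2_t - venous$c_o2, cv_co2_t - venous$c_co2,
           pv_n2_t - venous$pn2)
    new_cv_o2 <- venous$c_o2 + 0.6 * d[1]
    new_cv_co2 <- venous$c_co2 + 0.6 * d[2]
    new_pn2 <- max(venous$pn2 + 0.6 * d[3], 0)
    pr <- pressures_from_contents(new_cv_o2, new_cv_co2, ctx)
    venous <- as.list(blood_state(pr$po2, pr$pco2, new_pn2, ctx))
    if (all(abs(d) < c(0.001, 0.001, 0.01))) break
  }
  art <- pressures_from_contents(ca_o2, ca_co2, ctx)
  list(pa_o2 = art$po2, pa_co2 = art$pco2,
       pa_n2 = ca_n2 / lung_constants()$alpha_n2,
       pv_o2 = venous$po2, pv_co2 = venous$pco2)
}
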