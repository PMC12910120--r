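// Multicompartment steady-state gas exchange solver.
//
// Each gas-exchanging compartment is characterised by its V/Q ratio, where V
// is *expired* alveolar ventilation (West & Wagner convention).  Per unit
// expired ventilation VE = 1 and perfusion Q = 1/ratio, the steady state for
// gas g reads
//     VI * FI_g - VE * FA_g = U_g / 1000          (gas side, L/min)
//     U_g = 10 * Q * (Cc'_g - Cv_g)               (blood side, mL/min)
// with fractions of dry gas F = P / 713, inspired volume closed by the total
// balance, and PAN2 = 713 - PAO2 - PACO2.  Ventilation volumes are BTPS
// (body temperature, saturated) while blood contents are STPD, so gas-side
// volumes convert by 0.826 (= 273.15/310.15 * 713/760); equivalently each
// mm Hg of alveolar partial pressure carries 0.863 mL STPD per L BTPS.  The
// two independent unknowns (PAO2, PACO2) are found by damped Newton.

#include <Rcpp.h>
#include "blood.h"

using namespace Rcpp;
using namespace westvq;

namespace {

long g_resid_calls = 0;

struct Ctx { double hb, be, p50; };

const double BTPS_TO_STPD = (273.15 / 310.15) * (PDRY / PB);  // 0.82625
const double MMHG_TO_ML = PDRY / (1000.0 * BTPS_TO_STPD);     // 0.8629

struct CompState {
  double pao2, paco2;        // alveolar pressures (solution / warm start)
  double c_o2, c_co2, c_n2;  // end-capillary contents
  double ph_hint = 7.40;     // warm start for the Van Slyke Newton
  double j11, j12, j21, j22; // cached Jacobian (reused while it works)
  bool have_j = false;
  bool ok;
};

// residuals of the two independent per-compartment balances, in
// mm Hg * L/min; also returns end-capillary contents
inline void comp_resid(double pao2, double paco2, double ratio,
                       double pio2, const Ctx& c,
                       double cvo2, double cvco2, double cvn2,
                       double& r1, double& r2,
                       double& co, double& cc, double& cn,
                       double& ph_hint) {
  ++g_resid_calls;
  double pan2 = PDRY - pao2 - paco2;
  double ph = ph_from_pco2_be(paco2, c.hb, c.be, ph_hint);
  ph_hint = ph;
  double s  = o2_sat(pao2, ph, paco2, c.p50);
  co = o2_content(pao2, s, c.hb);
  cc = co2_content(paco2, ph, s, c.hb);
  cn = n2_content(pan2);
  double q10 = 10.0 / ratio;
  double uo2  = q10 * (co - cvo2);
  double uco2 = q10 * (cc - cvco2);
  double un2  = q10 * (cn - cvn2);
  double vi = 1.0 + (uo2 + uco2 + un2) / (1000.0 * BTPS_TO_STPD);
  r1 = vi * pio2 - pao2 - MMHG_TO_ML * uo2;
  r2 = -paco2 - MMHG_TO_ML * uco2;
}

// damped Newton on (PAO2, PACO2) with box constraints and a coarse
// grid-search fallback; warm-startable through st.pao2/st.paco2
bool solve_compartment(double ratio, double fio2, const Ctx& c,
                       double pvo2, double pvco2,
                       double cvo2, double cvco2, double cvn2,
                       CompState& st, double tol = 1e-6) {
  double pio2 = fio2 * PDRY;
  double x = st.pao2, y = st.paco2;
  if (!std::isfinite(x) || !std::isfinite(y) || x <= 0.0 || y <= 0.0) {
    // blend venous and inspired compositions by the V/Q ratio
    double t = ratio / (ratio + 1.0);
    x = pvo2 + (pio2 - pvo2) * t;
    y = std::max(1.0, pvco2 * (1.0 - t));
  }
  const double XLO = 1e-3, YLO = 1e-3, YHI = 400.0;
  auto clampxy = [&](double& px, double& py) {
    if (py < YLO) py = YLO;
    if (py > YHI) py = YHI;
    if (px < XLO) px = XLO;
    if (px > PDRY - py) px = PDRY - py;  // PAN2 >= 0, boundary attainable
  };
  clampxy(x, y);

  double r1, r2, co, cc, cn;
  double& ph = st.ph_hint;
  comp_resid(x, y, ratio, pio2, c, cvo2, cvco2, cvn2, r1, r2, co, cc, cn,
             ph);
  bool ok = false;
  for (int attempt = 0; attempt < 2 && !ok; ++attempt) {
    if (attempt == 1) {
      // fallback: coarse scan for the best starting point
      double best = 1e300, bx = x, by = y;
      for (int i = 0; i <= 40; ++i) {
        double px = std::exp(std::log(0.5) +
                    (std::log(PDRY - 1.0) - std::log(0.5)) * i / 40.0);
        for (int j = 0; j <= 30; ++j) {
          double py = std::exp(std::log(0.5) +
                      (std::log(250.0) - std::log(0.5)) * j / 30.0);
          if (px + py > PDRY - 1.0) continue;
          double t1, t2, a, b, d;
          comp_resid(px, py, ratio, pio2, c, cvo2, cvco2, cvn2,
                     t1, t2, a, b, d, ph);
          double n = std::fabs(t1) + std::fabs(t2);
          if (n < best) { best = n; bx = px; by = py; }
        }
      }
      x = bx; y = by;
      comp_resid(x, y, ratio, pio2, c, cvo2, cvco2, cvn2,
                 r1, r2, co, cc, cn, ph);
    }
    bool fresh_j = false;
    for (int it = 0; it < 60; ++it) {
      double n0 = std::fabs(r1) + std::fabs(r2);
      if (n0 < tol) { ok = true; break; }
      if (!st.have_j) {
        double hx = 1e-5 * (1.0 + std::fabs(x));
        double hy = 1e-5 * (1.0 + std::fabs(y));
        double a1, a2, b1, b2, d1, d2, d3;
        comp_resid(x + hx, y, ratio, pio2, c, cvo2, cvco2, cvn2,
                   a1, a2, d1, d2, d3, ph);
        comp_resid(x, y + hy, ratio, pio2, c, cvo2, cvco2, cvn2,
                   b1, b2, d1, d2, d3, ph);
        st.j11 = (a1 - r1) / hx; st.j12 = (b1 - r1) / hy;
        st.j21 = (a2 - r2) / hx; st.j22 = (b2 - r2) / hy;
        st.have_j = true;
        fresh_j = true;
      }
      double det = st.j11 * st.j22 - st.j12 * st.j21;
      if (std::fabs(det) < 1e-300) {
        if (fresh_j) break;
        st.have_j = false;
        continue;
      }
      double dx = -( r1 * st.j22 - r2 * st.j12) / det;
      double dy = -(-r1 * st.j21 + r2 * st.j11) / det;
      double lambda = 1.0;
      bool moved = false;
      for (int h = 0; h < 10; ++h) {
        double xn = x + lambda * dx, yn = y + lambda * dy;
        clampxy(xn, yn);
        double t1, t2, e1, e2, e3;
        comp_resid(xn, yn, ratio, pio2, c, cvo2, cvco2, cvn2,
                   t1, t2, e1, e2, e3, ph);
        if (std::fabs(t1) + std::fabs(t2) < n0) {
          x = xn; y = yn; r1 = t1; r2 = t2; co = e1; cc = e2; cn = e3;
          moved = true;
          break;
        }
        lambda *= 0.5;
      }
      if (!moved) {
        // no progress: with a Jacobian computed at this very point the
        // Newton direction is exhausted -> fall back to the grid scan;
        // otherwise refresh the cache and retry
        if (fresh_j) break;
        st.have_j = false;
        fresh_j = false;
        continue;
      }
      // the point moved; keep the cached Jacobian only while it still
      // delivers Newton-like contraction, else refresh next iteration
      fresh_j = false;
      if (lambda < 0.9 || std::fabs(r1) + std::fabs(r2) > 0.2 * n0) {
        st.have_j = false;
      }
    }
  }
  st.pao2 = x; st.paco2 = y;
  st.c_o2 = co; st.c_co2 = cc; st.c_n2 = cn;
  st.ok = ok;
  return ok;
}

struct LungConfig {
  int n_comp;
  double ratio_lo, ratio_hi;
  double damping;
  int max_iter;
  double tol_o2, tol_co2, tol_pn2;
};

LungConfig read_config(const List& config) {
  LungConfig cf;
  cf.n_comp   = as<int>(config["n_compartments"]);
  cf.ratio_lo = as<double>(config["ratio_min"]);
  cf.ratio_hi = as<double>(config["ratio_max"]);
  cf.damping  = as<double>(config["damping"]);
  cf.max_iter = as<int>(config["max_iter"]);
  cf.tol_o2   = as<double>(config["tol_cv_o2"]);
  cf.tol_co2  = as<double>(config["tol_cv_co2"]);
  cf.tol_pn2  = as<double>(config["tol_pv_n2"]);
  return cf;
}

struct CaseResult {
  double pao2, paco2, pan2, ph_a, sao2, ca_o2, ca_co2;
  double pvo2, pvco2, pvn2, ph_v, svo2, cv_o2, cv_co2;
  double qva, va, mpaco2, vd_alv;
  bool converged, feasible;
  int n_iter;
};

// Solve a whole case.  Optionally fills per-compartment vectors.
bool solve_case(double shunt, double logsd, double meanvq, double fio2,
                double vco2, double rq, double qt, const Ctx& c,
                const LungConfig& cf, CaseResult& out,
                std::vector<double>* ratios_out = nullptr,
                std::vector<double>* qfrac_out = nullptr,
                std::vector<double>* pao2_out = nullptr,
                std::vector<double>* paco2_out = nullptr,
                std::vector<double>* pan2_out = nullptr,
                const std::vector<double>* ratios_in = nullptr,
                const std::vector<double>* qfrac_in = nullptr) {
  out = CaseResult();
  out.converged = false;
  out.feasible = true;
  out.qva = NA_REAL;

  // perfusion-weighted lognormal distribution on a fixed log-spaced grid
  int n = cf.n_comp;
  std::vector<double> ratio(n), w(n);
  if (ratios_in) {
    n = (int)ratios_in->size();
    ratio = *ratios_in;
    w = *qfrac_in;
  } else {
    double llo = std::log(cf.ratio_lo), lhi = std::log(cf.ratio_hi);
    // meanvq is the perfusion-weighted arithmetic mean unit V/Q ratio
    // (MIGET first-moment convention), so the lognormal location is
    // ln(meanvq) - logsd^2 / 2
    double sd = std::max(logsd, 1e-6);
    double mu = std::log(meanvq) - 0.5 * sd * sd;
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double lr = llo + (lhi - llo) * i / (n - 1.0);
      ratio[i] = std::exp(lr);
      double z = (lr - mu) / sd;
      w[i] = std::exp(-0.5 * z * z);
      wsum += w[i];
    }
    if (wsum <= 0.0) return false;  // degenerate distribution
    for (int i = 0; i < n; ++i) w[i] /= wsum;
  }
  double sh = shunt / 100.0;
  double qnb = (1.0 - sh) * qt;           // non-shunt blood flow, L/min
  double va = 0.0;
  for (int i = 0; i < n; ++i) va += ratio[i] * w[i] * qnb;
  out.va = va;

  double vo2 = vco2 / rq;
  double pio2 = fio2 * PDRY;
  double pin2 = (1.0 - fio2) * PDRY;

  // strict upper bound on the steady-state venous O2 content: arterial
  // content cannot exceed fully saturated end-capillary blood at PIO2, and
  // shunt recirculation only lowers it.  If even this bound leaves no
  // positive venous content the case has no steady state (reported with
  // pv_o2 = 0 so the PvO2 > 0 inclusion range rejects it).
  double c_max = O2CAP * c.hb + O2SOL * pio2;
  if (c_max - vo2 / (10.0 * qt * std::max(1.0 - sh, 1e-6)) < 0.01) {
    out.feasible = false;
    out.pvo2 = 0.0;
    out.n_iter = 0;
    return false;
  }

  // initial mixed-venous state
  double pvo2 = 40.0, pvco2 = 46.0;
  double pvn2 = (fio2 < 0.995) ? pin2 : 10.0;
  BloodGas v = blood_from_pressures(pvo2, pvco2, pvn2, c.hb, c.be, c.p50);
  double cvo2 = v.c_o2, cvco2 = v.c_co2, cvn2 = v.c_n2;

  std::vector<CompState> st(n);
  for (int i = 0; i < n; ++i) { st[i].pao2 = NA_REAL; st[i].paco2 = NA_REAL; }

  double cao2 = NA_REAL, caco2 = NA_REAL, can2 = NA_REAL;
  bool all_ok = true;
  int it = 0;
  double pd1 = 0.0, pd2 = 0.0, pd3 = 0.0;  // previous raw updates (Aitken)
  for (it = 1; it <= cf.max_iter; ++it) {
    double mo = 0.0, mc = 0.0, mn = 0.0;
    all_ok = true;
    for (int i = 0; i < n; ++i) {
      if (it > 60) st[i].have_j = false;  // stragglers get exact Newton
      // coarse-to-fine: early venous iterates only need approximate
      // compartment solves; the final iterations use the full tolerance
      double itol = (it <= 3) ? 1e-4 : 1e-6;
      if (it == 1 && i > 0 && !std::isfinite(st[i].pao2) &&
          std::isfinite(st[i - 1].pao2)) {
        // cold start from the neighbouring compartment: alveolar
        // pressures vary smoothly along the V/Q grid
        st[i].pao2 = st[i - 1].pao2;
        st[i].paco2 = st[i - 1].paco2;
      }
      bool ok = solve_compartment(ratio[i], fio2, c, pvo2, pvco2,
                                  cvo2, cvco2, cvn2, st[i], itol);
      all_ok = all_ok && ok;
      mo += w[i] * st[i].c_o2;
      mc += w[i] * st[i].c_co2;
      mn += w[i] * st[i].c_n2;
    }
    cao2  = sh * cvo2  + (1.0 - sh) * mo;
    caco2 = sh * cvco2 + (1.0 - sh) * mc;
    can2  = sh * cvn2  + (1.0 - sh) * mn;

    double cvo2_t  = cao2  - vo2  / (10.0 * qt);
    double cvco2_t = caco2 + vco2 / (10.0 * qt);
    double pvn2_t  = can2 / ALPHA_N2;  // zero net N2 flux: Cv_N2 = Ca_N2

    if (cvo2_t < 0.01) { out.feasible = false; break; }

    double d1 = cvo2_t - cvo2, d2 = cvco2_t - cvco2, d3 = pvn2_t - pvn2;
    bool conv = std::fabs(d1) < cf.tol_o2 && std::fabs(d2) < cf.tol_co2 &&
                std::fabs(d3) < cf.tol_pn2;
    if (conv && all_ok) {
      // stop *before* updating: the compartment solutions, mixed
      // contents and venous state all belong to the same iterate
      out.converged = true;
      break;
    }
    // successive substitution with Aitken-style over-relaxation: the
    // componentwise update ratio rho estimates the linear contraction
    // rate, so the extrapolated step 1/(1 - rho) jumps near the fixed
    // point; clamped and only engaged once the ratio is stable
    double b1 = cf.damping, b2 = cf.damping, b3 = cf.damping;
    if (it >= 2) {
      auto accel = [&](double d, double pd, double bdef) {
        if (std::fabs(pd) < 1e-14) return bdef;
        double rho = d / pd;
        if (!std::isfinite(rho) || rho > 0.998 || rho < -0.9) return bdef;
        double beta = bdef / (1.0 - rho);
        return std::min(std::max(beta, 0.2), 100.0);
      };
      b1 = accel(d1, pd1, cf.damping);
      b2 = accel(d2, pd2, cf.damping);
      b3 = accel(d3, pd3, cf.damping);
    }
    pd1 = d1; pd2 = d2; pd3 = d3;
    cvo2  += b1 * d1;
    cvco2 += b2 * d2;
    pvn2  += b3 * d3;
    if (cvo2 < 0.02) cvo2 = 0.02;
    if (cvco2 < 1.0) cvco2 = 1.0;
    if (pvn2 < 0.0) pvn2 = 0.0;
    cvn2 = n2_content(pvn2);
    if (!pressures_from_contents(cvo2, cvco2, c.hb, c.be, c.p50,
                                 pvo2, pvco2)) {
      out.feasible = false;
      break;
    }
  }
  out.n_iter = it;
  if (!out.feasible) {
    out.pvo2 = 0.0;  // reported so the PvO2 > 0 inclusion range rejects it
    return false;
  }
  if (!out.converged) return false;

  // arterial state from mixed contents
  double pao2 = 90.0, paco2 = 40.0;
  if (!pressures_from_contents(cao2, caco2, c.hb, c.be, c.p50,
                               pao2, paco2)) {
    out.converged = false;
    return false;
  }
  double ph_a = ph_from_pco2_be(paco2, c.hb, c.be);
  out.pao2 = pao2; out.paco2 = paco2;
  out.pan2 = can2 / ALPHA_N2;
  out.ph_a = ph_a;
  out.sao2 = o2_sat(pao2, ph_a, paco2, c.p50);
  out.ca_o2 = cao2; out.ca_co2 = caco2;
  out.pvo2 = pvo2; out.pvco2 = pvco2; out.pvn2 = pvn2;
  out.ph_v = ph_from_pco2_be(pvco2, c.hb, c.be);
  out.svo2 = o2_sat(pvo2, out.ph_v, pvco2, c.p50);
  out.cv_o2 = cvo2; out.cv_co2 = cvco2;

  // ventilation-weighted mean alveolar PCO2 and alveolar dead-space fraction
  double mp = 0.0;
  for (int i = 0; i < n; ++i) mp += ratio[i] * w[i] * qnb * st[i].paco2;
  mp /= va;
  out.mpaco2 = mp;
  double vd = 100.0 * (paco2 - mp) / paco2;
  out.vd_alv = std::min(std::max(vd, 0.0), 99.999);

  // Riley venous admixture against the ideal compartment (PACO2 = PaCO2,
  // alveolar gas equation for ideal PAO2)
  double pao2_i = pio2 - paco2 * (fio2 + (1.0 - fio2) / rq);
  if (pao2_i > 0.5) {
    double s_i = o2_sat(pao2_i, ph_a, paco2, c.p50);
    double cc_i = o2_content(pao2_i, s_i, c.hb);
    if (cc_i > cvo2 + 1e-9) {
      double qva = 100.0 * (cc_i - cao2) / (cc_i - cvo2);
      out.qva = qva;
    }
  }

  if (ratios_out) {
    ratios_out->assign(ratio.begin(), ratio.end());
    qfrac_out->assign(w.begin(), w.end());
    pao2_out->resize(n); paco2_out->resize(n); pan2_out->resize(n);
    for (int i = 0; i < n; ++i) {
      (*pao2_out)[i] = st[i].pao2;
      (*paco2_out)[i] = st[i].paco2;
      (*pan2_out)[i] = PDRY - st[i].pao2 - st[i].paco2;
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
double cpp_resid_calls(bool reset = true) {
  double v = (double)g_resid_calls;
  if (reset) g_resid_calls = 0;
  return v;
}

// ---- exported blood chemistry kernels (vectorized) ----

// [[Rcpp::export]]
NumericVector cpp_ph_from_pco2_be(NumericVector pco2, NumericVector hb,
                                  NumericVector be) {
  int n = pco2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ph_from_pco2_be(pco2[i], hb[i], be[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_o2_sat(NumericVector po2, NumericVector ph,
                         NumericVector pco2, NumericVector p50) {
  int n = po2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = o2_sat(po2[i], ph[i], pco2[i], p50[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_co2_content(NumericVector pco2, NumericVector ph,
                              NumericVector so2, NumericVector hb) {
  int n = pco2.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = co2_content(pco2[i], ph[i], so2[i], hb[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_blood_from_pressures(NumericVector po2, NumericVector pco2,
                              NumericVector pn2, NumericVector hb,
                              NumericVector be, NumericVector p50) {
  int n = po2.size();
  NumericVector vph(n), vso2(n), vco(n), vcc(n), vcn(n);
  for (int i = 0; i < n; ++i) {
    BloodGas b = blood_from_pressures(po2[i], pco2[i], pn2[i],
                                      hb[i], be[i], p50[i]);
    vph[i] = b.ph; vso2[i] = b.so2;
    vco[i] = b.c_o2; vcc[i] = b.c_co2; vcn[i] = b.c_n2;
  }
  return List::create(_["ph"] = vph, _["so2"] = vso2, _["c_o2"] = vco,
                      _["c_co2"] = vcc, _["c_n2"] = vcn);
}

// [[Rcpp::export]]
List cpp_pressures_from_contents(double c_o2, double c_co2, double hb,
                                 double be, double p50) {
  double po2 = 50.0, pco2 = 45.0;
  bool ok = pressures_from_contents(c_o2, c_co2, hb, be, p50, po2, pco2);
  return List::create(_["po2"] = po2, _["pco2"] = pco2, _["ok"] = ok);
}

// ---- exported compartment / lung solvers ----

// [[Rcpp::export]]
List cpp_solve_compartment(double ratio, double fio2,
                           double pvo2, double pvco2, double pvn2,
                           double hb, double be, double p50) {
  Ctx c{hb, be, p50};
  BloodGas v = blood_from_pressures(pvo2, pvco2, pvn2, hb, be, p50);
  CompState st;
  st.pao2 = NA_REAL; st.paco2 = NA_REAL;
  bool ok = solve_compartment(ratio, fio2, c, pvo2, pvco2,
                              v.c_o2, v.c_co2, v.c_n2, st);
  double pan2 = PDRY - st.pao2 - st.paco2;
  double q10 = 10.0 / ratio;
  double uo2 = q10 * (st.c_o2 - v.c_o2);
  double uco2 = q10 * (st.c_co2 - v.c_co2);
  double un2 = q10 * (st.c_n2 - v.c_n2);
  return List::create(
      _["pao2"] = st.pao2, _["paco2"] = st.paco2, _["pan2"] = pan2,
      _["cc_o2"] = st.c_o2, _["cc_co2"] = st.c_co2, _["cc_n2"] = st.c_n2,
      _["vi"] = 1.0 + (uo2 + uco2 + un2) / (1000.0 * BTPS_TO_STPD),
      _["flux_o2"] = uo2, _["flux_co2"] = uco2, _["flux_n2"] = un2,
      _["converged"] = ok);
}

// [[Rcpp::export]]
DataFrame cpp_solve_cases(DataFrame inputs, List config) {
  LungConfig cf = read_config(config);
  NumericVector shunt = inputs["shunt"], logsd = inputs["logsd"],
                meanvq = inputs["meanvq"], fio2 = inputs["fio2"],
                vco2 = inputs["vco2"], rq = inputs["rq"], hb = inputs["hb"],
                be = inputs["be"], p50 = inputs["p50"], qt = inputs["qt"];
  int n = shunt.size();
  NumericVector pao2(n), paco2(n), pan2(n), ph_a(n), sao2(n),
      pvo2(n), pvco2(n), pvn2(n), qva(n), va(n), mpaco2(n), vd_alv(n),
      ca_o2(n), ca_co2(n), cv_o2(n), cv_co2(n);
  LogicalVector converged(n), feasible(n);
  IntegerVector n_iter(n);
  for (int i = 0; i < n; ++i) {
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    Ctx c{hb[i], be[i], p50[i]};
    CaseResult r;
    bool ok = solve_case(shunt[i], logsd[i], meanvq[i], fio2[i], vco2[i],
                         rq[i], qt[i], c, cf, r);
    converged[i] = r.converged;
    feasible[i] = r.feasible;
    n_iter[i] = r.n_iter;
    va[i] = r.va;
    if (ok) {
      pao2[i] = r.pao2; paco2[i] = r.paco2; pan2[i] = r.pan2;
      ph_a[i] = r.ph_a; sao2[i] = r.sao2;
      pvo2[i] = r.pvo2; pvco2[i] = r.pvco2; pvn2[i] = r.pvn2;
      qva[i] = r.qva; mpaco2[i] = r.mpaco2; vd_alv[i] = r.vd_alv;
      ca_o2[i] = r.ca_o2; ca_co2[i] = r.ca_co2;
      cv_o2[i] = r.cv_o2; cv_co2[i] = r.cv_co2;
    } else {
      pao2[i] = NA_REAL; paco2[i] = NA_REAL; pan2[i] = NA_REAL;
      ph_a[i] = NA_REAL; sao2[i] = NA_REAL;
      pvo2[i] = r.feasible ? NA_REAL : 0.0;
      pvco2[i] = NA_REAL; pvn2[i] = NA_REAL;
      qva[i] = NA_REAL; mpaco2[i] = NA_REAL; vd_alv[i] = NA_REAL;
      ca_o2[i] = NA_REAL; ca_co2[i] = NA_REAL;
      cv_o2[i] = NA_REAL; cv_co2[i] = NA_REAL;
    }
  }
  return DataFrame::create(
      _["pa_o2"] = pao2, _["pa_co2"] = paco2, _["pa_n2"] = pan2,
      _["ph"] = ph_a, _["sa_o2"] = sao2,
      _["pv_o2"] = pvo2, _["pv_co2"] = pvco2, _["pv_n2"] = pvn2,
      _["ca_o2"] = ca_o2, _["ca_co2"] = ca_co2,
      _["cv_o2"] = cv_o2, _["cv_co2"] = cv_co2,
      _["qva"] = qva, _["va"] = va, _["mpaco2"] = mpaco2,
      _["vd_alv"] = vd_alv,
      _["converged"] = converged, _["feasible"] = feasible,
      _["n_iter"] = n_iter);
}

// [[Rcpp::export]]
List cpp_solve_lung_detail(double shunt, double logsd, double meanvq,
                           double fio2, double vco2, double rq, double qt,
                           double hb, double be, double p50, List config,
                           Nullable<NumericVector> ratios_custom = R_NilValue,
                           Nullable<NumericVector> qfrac_custom = R_NilValue) {
  LungConfig cf = read_config(config);
  Ctx c{hb, be, p50};
  CaseResult r;
  std::vector<double> rt, wv, p1, p2, p3;
  bool ok;
  if (ratios_custom.isNotNull()) {
    NumericVector rr(ratios_custom), ww(qfrac_custom);
    std::vector<double> rin(rr.begin(), rr.end()), win(ww.begin(), ww.end());
    double s = 0.0;
    for (double x : win) s += x;
    for (double& x : win) x /= s;
    ok = solve_case(shunt, logsd, meanvq, fio2, vco2, rq, qt, c, cf, r,
                    &rt, &wv, &p1, &p2, &p3, &rin, &win);
  } else {
    ok = solve_case(shunt, logsd, meanvq, fio2, vco2, rq, qt, c, cf, r,
                    &rt, &wv, &p1, &p2, &p3);
  }
  return List::create(
      _["ok"] = ok, _["converged"] = r.converged, _["feasible"] = r.feasible,
      _["n_iter"] = r.n_iter,
      _["pa_o2"] = r.pao2, _["pa_co2"] = r.paco2, _["pa_n2"] = r.pan2,
      _["ph"] = r.ph_a, _["sa_o2"] = r.sao2,
      _["pv_o2"] = r.pvo2, _["pv_co2"] = r.pvco2, _["pv_n2"] = r.pvn2,
      _["ca_o2"] = r.ca_o2, _["ca_co2"] = r.ca_co2,
      _["cv_o2"] = r.cv_o2, _["cv_co2"] = r.cv_co2,
      _["qva"] = r.qva, _["va"] = r.va, _["mpaco2"] = r.mpaco2,
      _["vd_alv"] = r.vd_alv,
      _["ratio"] = rt, _["q_frac"] = wv,
      _["comp_pao2"] = p1, _["comp_paco2"] = p2, _["comp_pan2"] = p3);
}
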