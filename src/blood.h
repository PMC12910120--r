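#ifndef WESTVQ_BLOOD_H
#define WESTVQ_BLOOD_H

#include <cmath>
#include <algorithm>

namespace westvq {

// Physical constants (37 C, sea level); see lung_constants() on the R side.
const double PB       = 760.0;   // barometric pressure, mm Hg
const double PH2O     = 47.0;    // water vapour pressure at 37 C, mm Hg
const double PDRY     = 713.0;   // PB - PH2O
const double O2CAP    = 1.39;    // mL O2 per g Hb
const double O2SOL    = 0.003;   // mL/dL/mm Hg dissolved O2
const double ALPHA_N2 = 0.0014;  // mL/dL/mm Hg dissolved N2 in whole blood
const double P50STD   = 26.86;   // reference P50 of the standard ODC, mm Hg
const double LN10     = 2.302585092994046;

inline double exp10(double x) { return std::exp(LN10 * x); }

// Siggaard-Andersen Van Slyke relation:
//   BE = (1 - 0.0143 Hb) * [(HCO3 - 24.4) + (1.63 Hb + 9.5) (pH - 7.40)]
// with HCO3 = 0.0307 * PCO2 * 10^(pH - 6.1).  Solved for pH by Newton;
// the left side is strictly increasing in pH so convergence is global.
inline double ph_from_pco2_be(double pco2, double hb, double be,
                              double ph0 = 7.40) {
  double ph = ph0;
  if (ph < 6.0 || ph > 8.5 || !std::isfinite(ph)) ph = 7.40;
  for (int i = 0; i < 60; ++i) {
    double hco3 = 0.0307 * pco2 * exp10(ph - 6.1);
    double f  = (1.0 - 0.0143 * hb) *
                ((hco3 - 24.4) + (1.63 * hb + 9.5) * (ph - 7.40)) - be;
    double df = (1.0 - 0.0143 * hb) * (hco3 * LN10 + (1.63 * hb + 9.5));
    double step = f / df;
    ph -= step;
    if (ph < 6.0) ph = 6.0;
    if (ph > 8.5) ph = 8.5;
    if (std::fabs(step) < 1e-9) break;
  }
  return ph;
}

// Severinghaus (1979) standard dissociation curve, S = (x^3 + 150 x) /
// (x^3 + 150 x + 23400), evaluated at PO2 rescaled by the effective in-vivo
// P50.  The Bohr shift moves log10(P50) by -0.48 per pH unit and +0.06 per
// log10(PCO2) decade away from (7.40, 40 mm Hg); the standard P50 input
// rescales the whole curve.
inline double p50_effective(double ph, double pco2, double p50_std) {
  double shift = -0.48 * (ph - 7.40) +
                  0.06 * (std::log10(std::max(pco2, 1e-3)) -
                          1.6020599913279624);
  return p50_std * exp10(shift);
}

inline double o2_sat(double po2, double ph, double pco2, double p50_std) {
  double p50 = p50_effective(ph, pco2, p50_std);
  double x = po2 * P50STD / p50;
  double poly = x * x * x + 150.0 * x;
  return poly / (poly + 23400.0);
}

inline double o2_content(double po2, double so2, double hb) {
  return O2CAP * hb * so2 + O2SOL * po2;
}

// Douglas et al. (1988) whole-blood CO2 content.  Plasma content from
// Henderson-Hasselbalch with pH-dependent pK', corrected to whole blood by
// a haemoglobin/saturation factor (Haldane effect).  The pH entering the
// correction factor is clamped to [6.5, 7.9]: beyond that the published
// factor changes sign (denominator 8.142 - pH), which is outside the
// relation's validity and would destabilise root finding in extreme
// high-V/Q compartments.
inline double co2_content(double pco2, double ph, double so2, double hb) {
  double phc = std::min(std::max(ph, 6.5), 7.9);
  double pk  = 6.086 + 0.042 * (7.40 - phc) +
               (38.0 - 37.0) * (0.00472 + 0.00139 * (7.40 - phc));
  double plasma = 0.0307 * pco2 * (1.0 + exp10(phc - pk));  // mmol/L
  double hbf = 1.0 - (0.0289 * hb) /
               ((3.352 - 0.456 * so2) * (8.142 - phc));
  return plasma * hbf * 2.226;  // mL/dL (22.26 mL CO2 per mmol)
}

inline double n2_content(double pn2) { return ALPHA_N2 * pn2; }

struct BloodGas {
  double po2, pco2, pn2, ph, so2, c_o2, c_co2, c_n2;
};

// Forward map: pressures + context -> full blood state.
inline BloodGas blood_from_pressures(double po2, double pco2, double pn2,
                                     double hb, double be, double p50) {
  BloodGas b;
  b.po2 = po2; b.pco2 = pco2; b.pn2 = pn2;
  b.ph  = ph_from_pco2_be(pco2, hb, be);
  b.so2 = o2_sat(po2, b.ph, pco2, p50);
  b.c_o2  = o2_content(po2, b.so2, hb);
  b.c_co2 = co2_content(pco2, b.ph, b.so2, hb);
  b.c_n2  = n2_content(pn2);
  return b;
}

// Inverse map: (O2 content, CO2 content) -> (PO2, PCO2), 2-D Newton with a
// nested-bisection fallback.  Warm-startable.  Returns false on failure.
inline bool pressures_from_contents(double c_o2, double c_co2,
                                    double hb, double be, double p50,
                                    double& po2, double& pco2) {
  const double PO2_LO = 0.02, PO2_HI = 1400.0;
  const double PCO2_LO = 0.2, PCO2_HI = 600.0;
  double x = po2, y = pco2;
  if (!(x > PO2_LO && x < PO2_HI)) x = 50.0;
  if (!(y > PCO2_LO && y < PCO2_HI)) y = 45.0;

  auto resid = [&](double p, double q, double& g1, double& g2) {
    double ph = ph_from_pco2_be(q, hb, be);
    double s  = o2_sat(p, ph, q, p50);
    g1 = o2_content(p, s, hb) - c_o2;
    g2 = co2_content(q, ph, s, hb) - c_co2;
  };

  double g1, g2;
  resid(x, y, g1, g2);
  bool ok = false;
  for (int it = 0; it < 60; ++it) {
    double n0 = std::fabs(g1) + std::fabs(g2);
    if (n0 < 1e-9) { ok = true; break; }
    double hx = 1e-5 * (1.0 + std::fabs(x));
    double hy = 1e-5 * (1.0 + std::fabs(y));
    double a1, a2, b1, b2;
    resid(x + hx, y, a1, a2);
    resid(x, y + hy, b1, b2);
    double j11 = (a1 - g1) / hx, j12 = (b1 - g1) / hy;
    double j21 = (a2 - g2) / hx, j22 = (b2 - g2) / hy;
    double det = j11 * j22 - j12 * j21;
    if (std::fabs(det) < 1e-14) break;
    double dx = -( g1 * j22 - g2 * j12) / det;
    double dy = -(-g1 * j21 + g2 * j11) / det;
    double lambda = 1.0;
    for (int h = 0; h < 8; ++h) {
      double xn = std::min(std::max(x + lambda * dx, PO2_LO), PO2_HI);
      double yn = std::min(std::max(y + lambda * dy, PCO2_LO), PCO2_HI);
      double t1, t2;
      resid(xn, yn, t1, t2);
      if (std::fabs(t1) + std::fabs(t2) < n0 || h == 7) {
        x = xn; y = yn; g1 = t1; g2 = t2;
        break;
      }
      lambda *= 0.5;
    }
  }
  if (!ok && std::fabs(g1) + std::fabs(g2) < 1e-6) ok = true;

  if (!ok) {
    // alternating nested bisection: each content is monotone in its own
    // pressure at fixed companion pressure
    x = 50.0; y = 45.0;
    for (int it = 0; it < 80; ++it) {
      double ph = ph_from_pco2_be(y, hb, be);
      double lo = PO2_LO, hi = PO2_HI;
      for (int b = 0; b < 60; ++b) {
        double mid = 0.5 * (lo + hi);
        double s = o2_sat(mid, ph, y, p50);
        if (o2_content(mid, s, hb) < c_o2) lo = mid; else hi = mid;
      }
      x = 0.5 * (lo + hi);
      double s_now = o2_sat(x, ph, y, p50);
      lo = PCO2_LO; hi = PCO2_HI;
      for (int b = 0; b < 60; ++b) {
        double mid = 0.5 * (lo + hi);
        double phm = ph_from_pco2_be(mid, hb, be);
        if (co2_content(mid, phm, s_now, hb) < c_co2) lo = mid; else hi = mid;
      }
      double ynew = 0.5 * (lo + hi);
      double dy = std::fabs(ynew - y);
      y = ynew;
      if (dy < 1e-7) break;
    }
    resid(x, y, g1, g2);
    ok = std::fabs(g1) + std::fabs(g2) < 1e-4;
  }
  po2 = x; pco2 = y;
  return ok;
}

}  // namespace westvq

#endif
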