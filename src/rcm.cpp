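// Core numerics for the red-cell homeostasis simulator.
//
// Unit conventions (documented in the package help):
//   amounts   Q*  : mmol per liter of original cells (mmol/Loc)
//   fluxes    J*  : mmol/Loch, net influx positive (efflux negative)
//   concs     C*  : mmol per liter cell water (mmol/Lcw); plasma mmol/L
//   permeabilities: h^-1 (1 h^-1 ~ 2e-8 cm/s for the standardized cell)
//   Em        : mV;  RT/F = 26.73 mV at 37 C
//
// The fast "equilibration" applied after every flux step solves, at fixed
// cation/divalent contents, the joint (pHi, Vw, QA) satisfying
//   (i)  rH = rA        (Jacobs-Stewart anion-exchanger/CO2-shunt limit)
//   (ii) electroneutrality with nHb from the Dalmark titration line
//   (iii) osmotic equality including the hemoglobin virial term fHb*CHb
// and then the zero-net-current membrane potential (Goldman leak currents
// plus the electrogenic 3:2 Na pump and PMCA currents).

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double RTF = 26.73;  // mV at 37 C

// ---- parameter vector layout (see R/params.R pack_params) ----------------
enum {
  P_CNao = 0, P_CKo, P_CAo, P_pHo, P_CaO, P_MgO, P_Osmo,
  P_alpha, P_pIoxy, P_pIdeoxy, P_b1, P_b2,
  P_QHb, P_QX, P_nX,
  P_PNa, P_PK, P_PA, P_PCa, P_PMg,
  P_PzNa, P_PzK, P_PzA, P_PzCa, P_PzMg,
  P_naFmax, P_KmNa, P_KiK, P_KMg,
  P_caFmax, P_KmCa,
  P_gPKmax, P_K05Ca, P_hill,
  P_kcl,
  P_inh,
  P_QATP, P_QBPG, P_KdATPo, P_KdATPd, P_KdBPGo, P_KdBPGd, P_cabr,
  NPAR
};

// ---- state vector layout --------------------------------------------------
enum {
  S_Vw = 0, S_QNa, S_QK, S_QA, S_QCaT, S_QMgT,
  S_pHi, S_Em, S_CaF, S_MgF, S_oxy,
  NSTATE
};

// ---- scalar Brent root finder --------------------------------------------
template <class F>
static double brentq(F f, double a, double b, double fa, double fb,
                     double xtol, int maxit, bool &ok) {
  ok = true;
  if (fa == 0.0) return a;
  if (fb == 0.0) return b;
  if (fa * fb > 0.0) { ok = false; return NA_REAL; }
  double c = a, fc = fa, d = b - a, e = d;
  for (int it = 0; it < maxit; ++it) {
    if (std::fabs(fc) < std::fabs(fb)) {
      a = b; b = c; c = a; fa = fb; fb = fc; fc = fa;
    }
    double tol = 2.0 * DBL_EPSILON * std::fabs(b) + 0.5 * xtol;
    double m = 0.5 * (c - b);
    if (std::fabs(m) <= tol || fb == 0.0) return b;
    if (std::fabs(e) < tol || std::fabs(fa) <= std::fabs(fb)) {
      d = m; e = m;
    } else {
      double s = fb / fa, p, q;
      if (a == c) { p = 2.0 * m * s; q = 1.0 - s; }
      else {
        double r = fb / fc; q = fa / fc;
        p = s * (2.0 * m * q * (q - r) - (b - a) * (r - 1.0));
        q = (q - 1.0) * (r - 1.0) * (s - 1.0);
      }
      if (p > 0.0) q = -q; else p = -p;
      if (2.0 * p < std::min(3.0 * m * q - std::fabs(tol * q), std::fabs(e * q))) {
        e = d; d = p / q;
      } else { d = m; e = m; }
    }
    a = b; fa = fb;
    b += (std::fabs(d) > tol) ? d : (m > 0 ? tol : -tol);
    fb = f(b);
    if ((fb > 0) == (fc > 0)) { c = a; fc = fa; e = b - a; d = e; }
  }
  ok = false;
  return b;
}

// ---- elementary pieces ----------------------------------------------------

// Constant-field (Goldman) flux, net influx positive.
static double ghk(double P, double z, double Em, double Ci, double Co) {
  if (P == 0.0) return 0.0;
  double u = z * Em / RTF;
  if (u > 200.0) u = 200.0; else if (u < -200.0) u = -200.0;
  if (std::fabs(u) < 1e-8) {
    // series about u = 0: efflux = P*[(Ci - Co) + u*(Ci + Co)/2] + O(u^2)
    return -P * ((Ci - Co) + 0.5 * u * (Ci + Co));
  }
  double em1 = std::expm1(-u);                 // e^{-u} - 1
  double efflux = P * u * (Ci - Co * (em1 + 1.0)) / (-em1);
  return -efflux;
}

// Dalmark titration line: net charge on Hb, Eq/mol.
static double hb_charge_c(double pHi, double pI, double alpha) {
  return alpha * (pHi - pI);
}

// Osmotic coefficient of hemoglobin (virial in CHb, mmol/Lcw).
static double fhb_c(double CHb, double b1, double b2) {
  return 1.0 + b1 * CHb + b2 * CHb * CHb;
}

// Free Mg from 1:1 mass-action binding to ATP and 2,3-BPG.
static double mg_free_c(double MgTcw, double ATPcw, double BPGcw,
                        double KdA, double KdB) {
  if (MgTcw <= 0.0) return 0.0;
  if (ATPcw <= 0.0 && BPGcw <= 0.0) return MgTcw;
  auto f = [&](double m) {
    return m + ATPcw * m / (m + KdA) + BPGcw * m / (m + KdB) - MgTcw;
  };
  bool ok;
  double lo = 0.0, hi = MgTcw;
  double r = brentq(f, lo, hi, f(lo), f(hi), 1e-14, 200, ok);
  if (!ok) stop("mg_free: root bracketing failed");
  return r;
}

struct Pars { const double *p; };

// Na/K pump: cubic Na site with competitive K inhibition of apparent Na
// affinity and Mg activation. Returns JNa (negative = extrusion).
static double na_pump_c(double CNa, double CK, double MgF, const double *p) {
  if (CNa <= 0.0) return 0.0;
  double Km_app = p[P_KmNa] * (1.0 + CK / p[P_KiK]);
  double s = CNa / (CNa + Km_app);
  double fmg = MgF / (MgF + p[P_KMg]);
  return -p[P_naFmax] * p[P_inh] * s * s * s * fmg;
}

static double pmca_c(double CaF, const double *p) {
  if (CaF <= 0.0) return 0.0;
  return -p[P_caFmax] * CaF / (CaF + p[P_KmCa]);
}

static double gardos_perm_c(double CaF, const double *p) {
  if (CaF <= 0.0) return 0.0;
  double h = p[P_hill];
  double ch = std::pow(CaF, h), kh = std::pow(p[P_K05Ca], h);
  return p[P_gPKmax] * ch / (ch + kh);
}

// ---- flux evaluation -------------------------------------------------------
// Fills J[] per species and per pathway; state must be equilibrated.
struct Fluxes {
  double JNa_g, JK_g, JA_g, JCa_g, JMg_g;      // ground electrodiffusive
  double JNa_z, JK_z, JA_z, JCa_z, JMg_z;      // PIEZO1 (deoxy, open)
  double JNa_p, JK_p;                          // Na/K pump
  double JCa_p;                                // PMCA
  double JK_gard;                              // Gardos
  double JK_kcl, JA_kcl;                       // K:Cl cotransport
  double na, k, a, ca, mg;                     // species totals
};

static Fluxes fluxes_c(const double *s, const double *p, double amp,
                       bool piezo_open) {
  Fluxes f = {};
  double Vw = s[S_Vw];
  double CNa = s[S_QNa] / Vw, CK = s[S_QK] / Vw, CA = s[S_QA] / Vw;
  double Em = s[S_Em], CaF = s[S_CaF], MgF = s[S_MgF];

  f.JNa_g = ghk(p[P_PNa], 1, Em, CNa, p[P_CNao]);
  f.JK_g  = ghk(p[P_PK],  1, Em, CK,  p[P_CKo]);
  f.JA_g  = ghk(p[P_PA], -1, Em, CA,  p[P_CAo]);
  f.JCa_g = ghk(p[P_PCa], 2, Em, CaF, p[P_CaO]);
  f.JMg_g = ghk(p[P_PMg], 2, Em, MgF, p[P_MgO]);

  if (piezo_open && amp > 0.0) {
    f.JNa_z = ghk(amp * p[P_PzNa], 1, Em, CNa, p[P_CNao]);
    f.JK_z  = ghk(amp * p[P_PzK],  1, Em, CK,  p[P_CKo]);
    f.JA_z  = ghk(amp * p[P_PzA], -1, Em, CA,  p[P_CAo]);
    f.JCa_z = ghk(amp * p[P_PzCa], 2, Em, CaF, p[P_CaO]);
    f.JMg_z = ghk(amp * p[P_PzMg], 2, Em, MgF, p[P_MgO]);
  }

  f.JNa_p = na_pump_c(CNa, CK, MgF, p);
  f.JK_p  = -(2.0 / 3.0) * f.JNa_p;
  f.JCa_p = pmca_c(CaF, p);
  f.JK_gard = ghk(gardos_perm_c(CaF, p), 1, Em, CK, p[P_CKo]);

  if (p[P_kcl] > 0.0) {
    double j = -p[P_kcl] * (CK * CA - p[P_CKo] * p[P_CAo]) / p[P_CAo];
    f.JK_kcl = j; f.JA_kcl = j;
  }

  f.na = f.JNa_g + f.JNa_z + f.JNa_p;
  f.k  = f.JK_g + f.JK_z + f.JK_p + f.JK_gard + f.JK_kcl;
  f.a  = f.JA_g + f.JA_z + f.JA_kcl;
  f.ca = f.JCa_g + f.JCa_z + f.JCa_p;
  f.mg = f.JMg_g + f.JMg_z;
  return f;
}

// ---- zero-current membrane potential --------------------------------------
// Sum of charge fluxes: Goldman leaks (+PIEZO1, +Gardos) for Na,K,A,Ca,Mg,
// the electrogenic 3:2 Na pump (net charge JNa_p + JK_p = JNa_p/3) and the
// electrogenic PMCA (2*JCa_p). K:Cl is electroneutral.
static double em_solve_c(const double *s, const double *p, double amp,
                         bool piezo_open) {
  double Vw = s[S_Vw];
  double CNa = s[S_QNa] / Vw, CK = s[S_QK] / Vw, CA = s[S_QA] / Vw;
  double CaF = s[S_CaF], MgF = s[S_MgF];
  double PNa = p[P_PNa], PK = p[P_PK], PA = p[P_PA];
  double PCa = p[P_PCa], PMg = p[P_PMg];
  if (piezo_open && amp > 0.0) {
    PNa += amp * p[P_PzNa]; PK += amp * p[P_PzK]; PA += amp * p[P_PzA];
    PCa += amp * p[P_PzCa]; PMg += amp * p[P_PzMg];
  }
  PK += gardos_perm_c(CaF, p);
  double JNa_p = na_pump_c(CNa, CK, MgF, p);
  double pump_current = JNa_p + (-(2.0 / 3.0) * JNa_p) + 2.0 * pmca_c(CaF, p);

  auto cur = [&](double Em) {
    return ghk(PNa, 1, Em, CNa, p[P_CNao])
         + ghk(PK, 1, Em, CK, p[P_CKo])
         - ghk(PA, -1, Em, CA, p[P_CAo])
         + 2.0 * ghk(PCa, 2, Em, CaF, p[P_CaO])
         + 2.0 * ghk(PMg, 2, Em, MgF, p[P_MgO])
         + pump_current;
  };
  bool ok;
  double lo = -160.0, hi = 80.0;
  double r = brentq(cur, lo, hi, cur(lo), cur(hi), 1e-10, 200, ok);
  if (!ok) stop("em_solve: no zero-current potential in [-160, 80] mV");
  return r;
}

// ---- fast equilibration ----------------------------------------------------
// Unknowns (pHi, Vw, QA) at fixed QNa,QK,QCaT,QMgT.
//  outer root in pHi: charge residual; CA(pHi) = CAo*10^(pHi-pHo) from rH=rA
//  inner root in Vw : osmotic residual at that CA
static void equilibrate_c(double *s, const double *p, double amp,
                          bool piezo_open) {
  bool oxy = s[S_oxy] > 0.5;
  double KdA = oxy ? p[P_KdATPo] : p[P_KdATPd];
  double KdB = oxy ? p[P_KdBPGo] : p[P_KdBPGd];
  double pI  = oxy ? p[P_pIoxy]  : p[P_pIdeoxy];
  double QNa = s[S_QNa], QK = s[S_QK], QCaT = s[S_QCaT], QMgT = s[S_QMgT];
  double QHb = p[P_QHb], QX = p[P_QX];

  // inner solve: Vw from osmotic equality at given CA
  auto solve_vw = [&](double CA, double &MgF, double &CaF) {
    auto osm = [&](double Vw) {
      double MgTcw = QMgT / Vw;
      double m = mg_free_c(MgTcw, p[P_QATP] / Vw, p[P_QBPG] / Vw, KdA, KdB);
      double cf = p[P_cabr] * QCaT / Vw;
      double CHb = QHb / Vw;
      return (QNa + QK + QX) / Vw + CA + m + cf
           + fhb_c(CHb, p[P_b1], p[P_b2]) * CHb - p[P_Osmo];
    };
    bool ok;
    double lo = 0.02, hi = 60.0;
    double flo = osm(lo), fhi = osm(hi);
    if (flo * fhi > 0.0) stop("equilibrate: osmotic balance has no solution (CA=%f)", CA);
    double Vw = brentq(osm, lo, hi, flo, fhi, 1e-13, 200, ok);
    if (!ok) stop("equilibrate: osmotic solve failed to converge");
    double MgTcw = QMgT / Vw;
    MgF = mg_free_c(MgTcw, p[P_QATP] / Vw, p[P_QBPG] / Vw, KdA, KdB);
    CaF = p[P_cabr] * QCaT / Vw;
    return Vw;
  };

  auto charge = [&](double pHi) {
    double CA = p[P_CAo] * std::pow(10.0, pHi - p[P_pHo]);
    // no osmotically admissible state once CA approaches total osmolarity
    if (CA >= p[P_Osmo] - 1.0) return -1e9 - CA;
    double MgF, CaF;
    double Vw = solve_vw(CA, MgF, CaF);
    double CHb = QHb / Vw;
    return (QNa + QK) / Vw + 2.0 * MgF + 2.0 * CaF - CA
         + hb_charge_c(pHi, pI, p[P_alpha]) * CHb + p[P_nX] * QX / Vw;
  };

  // bracket around previous pHi, widen as needed
  double c0 = s[S_pHi] > 4.5 && s[S_pHi] < 9.5 ? s[S_pHi] : 7.2;
  double lo = c0 - 0.05, hi = c0 + 0.05;
  double flo = charge(lo), fhi = charge(hi);
  int guard = 0;
  while (flo * fhi > 0.0 && guard < 60) {
    if (flo < 0.0) { lo -= 0.1; flo = charge(lo); }
    else { hi += 0.1; fhi = charge(hi); }
    ++guard;
    if (lo < 4.0 || hi > 10.0) break;
  }
  if (flo * fhi > 0.0)
    stop("equilibrate: cannot bracket pHi (charge residuals %f, %f at pH %f, %f)",
         flo, fhi, lo, hi);
  bool ok;
  double pHi = brentq(charge, lo, hi, flo, fhi, 1e-12, 200, ok);
  if (!ok) stop("equilibrate: pHi solve failed to converge");

  double CA = p[P_CAo] * std::pow(10.0, pHi - p[P_pHo]);
  double MgF, CaF;
  double Vw = solve_vw(CA, MgF, CaF);

  s[S_pHi] = pHi;
  s[S_Vw] = Vw;
  s[S_QA] = CA * Vw;
  s[S_MgF] = MgF;
  s[S_CaF] = CaF;
  s[S_Em] = em_solve_c(s, p, amp, piezo_open);
}

// ---- single explicit step with halving on positivity failure ---------------
static void step_c(double *s, const double *p, double dt_s, double amp,
                   bool piezo_open, Fluxes *fout) {
  double save[NSTATE];
  std::copy(s, s + NSTATE, save);
  double remaining = dt_s;
  double dt = dt_s;
  const double dt_min = dt_s / 1024.0;
  Fluxes f = {};
  while (remaining > 1e-12) {
    if (dt > remaining) dt = remaining;
    f = fluxes_c(s, p, amp, piezo_open);
    double h = dt / 3600.0;
    double QNa = s[S_QNa] + f.na * h;
    double QK  = s[S_QK]  + f.k  * h;
    double QA  = s[S_QA]  + f.a  * h;
    double QCa = s[S_QCaT] + f.ca * h;
    double QMg = s[S_QMgT] + f.mg * h;
    if (QNa <= 0.0 || QK <= 0.0 || QA <= 0.0 || QCa < 0.0 || QMg <= 0.0) {
      dt *= 0.5;
      if (dt < dt_min) {
        std::copy(save, save + NSTATE, s);
        stop("step: contents would go negative at dt below %f s", dt_min);
      }
      continue;
    }
    double QCa_old = s[S_QCaT];
    s[S_QNa] = QNa; s[S_QK] = QK; s[S_QA] = QA;
    s[S_QCaT] = QCa; s[S_QMgT] = QMg;
    equilibrate_c(s, p, amp, piezo_open);
    // Heun corrector for the stiff calcium subsystem (free-Ca relaxation
    // is only ~1 min): trapezoidal content update, other species explicit
    Fluxes f2 = fluxes_c(s, p, amp, piezo_open);
    double QCa_h = QCa_old + 0.5 * h * (f.ca + f2.ca);
    if (QCa_h < 0.0) {
      std::copy(save, save + NSTATE, s);
      dt *= 0.5;
      if (dt < dt_min)
        stop("step: contents would go negative at dt below %f s", dt_min);
      // re-run the whole remaining interval from the saved state
      remaining = dt_s;
      continue;
    }
    s[S_QCaT] = QCa_h;
    s[S_CaF] = p[P_cabr] * QCa_h / s[S_Vw];
    remaining -= dt;
  }
  if (fout) *fout = f;
}

// ===========================================================================
// exported interface
// ===========================================================================

static void check_len(const NumericVector &x, int n, const char *what) {
  if (x.size() != n) stop("%s must have length %d", what, n);
}

// [[Rcpp::export(name = ".cpp_ghk")]]
double cpp_ghk(double P, double z, double Em, double Ci, double Co) {
  return ghk(P, z, Em, Ci, Co);
}

// [[Rcpp::export(name = ".cpp_hb_charge")]]
double cpp_hb_charge(double pHi, double pI, double alpha) {
  return hb_charge_c(pHi, pI, alpha);
}

// [[Rcpp::export(name = ".cpp_fhb")]]
double cpp_fhb(double CHb, double b1, double b2) {
  return fhb_c(CHb, b1, b2);
}

// [[Rcpp::export(name = ".cpp_mg_free")]]
double cpp_mg_free(double MgTcw, double ATPcw, double BPGcw, double KdA,
                   double KdB) {
  return mg_free_c(MgTcw, ATPcw, BPGcw, KdA, KdB);
}

// [[Rcpp::export(name = ".cpp_na_pump")]]
NumericVector cpp_na_pump(double CNa, double CK, double MgF,
                          NumericVector pars) {
  check_len(pars, NPAR, "pars");
  double jna = na_pump_c(CNa, CK, MgF, pars.begin());
  return NumericVector::create(_["JNa_pump"] = jna,
                               _["JK_pump"] = -(2.0 / 3.0) * jna);
}

// [[Rcpp::export(name = ".cpp_pmca")]]
double cpp_pmca(double CaF, NumericVector pars) {
  check_len(pars, NPAR, "pars");
  return pmca_c(CaF, pars.begin());
}

// [[Rcpp::export(name = ".cpp_gardos_perm")]]
double cpp_gardos_perm(double CaF, NumericVector pars) {
  check_len(pars, NPAR, "pars");
  return gardos_perm_c(CaF, pars.begin());
}

// [[Rcpp::export(name = ".cpp_fluxes")]]
NumericVector cpp_fluxes(NumericVector state, NumericVector pars, double amp,
                         bool piezo_open) {
  check_len(state, NSTATE, "state");
  check_len(pars, NPAR, "pars");
  Fluxes f = fluxes_c(state.begin(), pars.begin(), amp, piezo_open);
  return NumericVector::create(
      _["JNa"] = f.na, _["JK"] = f.k, _["JA"] = f.a, _["JCaT"] = f.ca,
      _["JMgT"] = f.mg, _["JNa_ground"] = f.JNa_g, _["JK_ground"] = f.JK_g,
      _["JA_ground"] = f.JA_g, _["JCa_ground"] = f.JCa_g,
      _["JMg_ground"] = f.JMg_g, _["JNa_piezo"] = f.JNa_z,
      _["JK_piezo"] = f.JK_z, _["JA_piezo"] = f.JA_z,
      _["JCa_piezo"] = f.JCa_z, _["JMg_piezo"] = f.JMg_z,
      _["JNa_pump"] = f.JNa_p, _["JK_pump"] = f.JK_p,
      _["JCa_pump"] = f.JCa_p, _["JK_gardos"] = f.JK_gard,
      _["JK_kcl"] = f.JK_kcl);
}

// [[Rcpp::export(name = ".cpp_em_solve")]]
double cpp_em_solve(NumericVector state, NumericVector pars, double amp,
                    bool piezo_open) {
  check_len(state, NSTATE, "state");
  check_len(pars, NPAR, "pars");
  return em_solve_c(state.begin(), pars.begin(), amp, piezo_open);
}

// [[Rcpp::export(name = ".cpp_equilibrate")]]
NumericVector cpp_equilibrate(NumericVector state, NumericVector pars,
                              double amp, bool piezo_open) {
  check_len(state, NSTATE, "state");
  check_len(pars, NPAR, "pars");
  NumericVector out = clone(state);
  equilibrate_c(out.begin(), pars.begin(), amp, piezo_open);
  return out;
}

// [[Rcpp::export(name = ".cpp_step")]]
NumericVector cpp_step(NumericVector state, NumericVector pars, double dt_s,
                       double amp, bool piezo_open) {
  check_len(state, NSTATE, "state");
  check_len(pars, NPAR, "pars");
  NumericVector out = clone(state);
  step_c(out.begin(), pars.begin(), dt_s, amp, piezo_open, nullptr);
  return out;
}

// ---- full run ---------------------------------------------------------------
// schedule: matrix with columns kind (0 oxy, 1 deoxy, 2 lingering-deoxy),
//           duration_s, amplitude
// events:   matrix with columns time_h, par_index (0-based), value
// Returns list(ts = record matrix, transits = per-transit summary matrix).

static const char *TS_COLS[] = {
  "t", "relvol", "Vw", "QNa", "QK", "QA", "QCaT", "QMgT",
  "CNa", "CK", "CA", "CaF", "MgT", "MgF", "pHi", "Em",
  "EA", "EK", "ENa", "rA", "rH", "nHb", "Hb_charge", "fHb", "Hb_osm", "CX",
  "JNa_pump", "JK_pump", "JCa_pump", "JK_gardos", "JK_kcl",
  "JNa_ground", "JK_ground", "JA_ground", "JCa_ground",
  "JNa_piezo", "JK_piezo", "JA_piezo", "JCa_piezo", "JMg_piezo",
  "transit_kind", "amplitude"
};
static const int NTS = sizeof(TS_COLS) / sizeof(TS_COLS[0]);

static const char *TR_COLS[] = {
  "transit", "kind", "t_start", "t_end", "duration_s", "amplitude",
  "mean_relvol", "mean_pHi", "min_pHi", "mean_Em", "mean_CNa", "mean_CK",
  "mean_CA", "mean_MgT", "mean_MgF", "mean_CaF",
  "min_JNa_pump", "max_JNa_pump", "mean_JNa_pump", "mean_JCa_pump",
  "mean_JK_gardos", "mean_JNa_passive", "mean_Hb_osm"
};
static const int NTR = sizeof(TR_COLS) / sizeof(TR_COLS[0]);

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector state0, NumericVector pars,
                  NumericMatrix schedule, NumericMatrix events,
                  double dt_s, double record_s, double Vw_ref) {
  check_len(state0, NSTATE, "state0");
  check_len(pars, NPAR, "pars");
  if (schedule.ncol() != 3) stop("schedule must have 3 columns");
  if (events.ncol() != 0 && events.ncol() != 3) stop("events must have 3 columns");

  std::vector<double> p(pars.begin(), pars.end());
  double s[NSTATE];
  std::copy(state0.begin(), state0.end(), s);

  int ntr = schedule.nrow();
  double total_s = 0.0;
  for (int i = 0; i < ntr; ++i) total_s += schedule(i, 1);
  int max_rows = (int)(total_s / record_s) + 2 * ntr + events.nrow() + 16;

  NumericMatrix ts(max_rows, NTS);
  NumericMatrix tr(ntr, NTR);
  int nrow_ts = 0;

  double Vsolid = 1.0 - Vw_ref;
  double t_s = 0.0;            // simulation time, seconds
  double next_record = 0.0;
  int ev_i = 0;
  int nev = events.nrow();

  // sort event times ascending (expected already sorted; enforce)
  std::vector<int> ev_order(nev);
  for (int i = 0; i < nev; ++i) ev_order[i] = i;
  std::sort(ev_order.begin(), ev_order.end(), [&](int a, int b) {
    return events(a, 0) < events(b, 0);
  });

  auto record_row = [&](double amp, bool open, double kind) {
    if (nrow_ts >= max_rows) stop("internal: record buffer overflow");
    Fluxes f = fluxes_c(s, p.data(), amp, open);
    double Vw = s[S_Vw];
    double CNa = s[S_QNa] / Vw, CK = s[S_QK] / Vw, CA = s[S_QA] / Vw;
    bool oxy = s[S_oxy] > 0.5;
    double pI = oxy ? p[P_pIoxy] : p[P_pIdeoxy];
    double CHb = p[P_QHb] / Vw;
    double nHb = hb_charge_c(s[S_pHi], pI, p[P_alpha]);
    double fHb = fhb_c(CHb, p[P_b1], p[P_b2]);
    double rA = p[P_CAo] / CA;
    int j = 0;
    ts(nrow_ts, j++) = t_s / 3600.0;
    ts(nrow_ts, j++) = (Vw + Vsolid);
    ts(nrow_ts, j++) = Vw;
    ts(nrow_ts, j++) = s[S_QNa];
    ts(nrow_ts, j++) = s[S_QK];
    ts(nrow_ts, j++) = s[S_QA];
    ts(nrow_ts, j++) = s[S_QCaT];
    ts(nrow_ts, j++) = s[S_QMgT];
    ts(nrow_ts, j++) = CNa;
    ts(nrow_ts, j++) = CK;
    ts(nrow_ts, j++) = CA;
    ts(nrow_ts, j++) = s[S_CaF];
    ts(nrow_ts, j++) = s[S_QMgT] / Vw;
    ts(nrow_ts, j++) = s[S_MgF];
    ts(nrow_ts, j++) = s[S_pHi];
    ts(nrow_ts, j++) = s[S_Em];
    ts(nrow_ts, j++) = -RTF * std::log(rA);
    ts(nrow_ts, j++) = RTF * std::log(p[P_CKo] / CK);
    ts(nrow_ts, j++) = RTF * std::log(p[P_CNao] / CNa);
    ts(nrow_ts, j++) = rA;
    ts(nrow_ts, j++) = std::pow(10.0, p[P_pHo] - s[S_pHi]);
    ts(nrow_ts, j++) = nHb;
    ts(nrow_ts, j++) = nHb * CHb;
    ts(nrow_ts, j++) = fHb;
    ts(nrow_ts, j++) = fHb * CHb;
    ts(nrow_ts, j++) = p[P_QX] / Vw;
    ts(nrow_ts, j++) = f.JNa_p;
    ts(nrow_ts, j++) = f.JK_p;
    ts(nrow_ts, j++) = f.JCa_p;
    ts(nrow_ts, j++) = f.JK_gard;
    ts(nrow_ts, j++) = f.JK_kcl;
    ts(nrow_ts, j++) = f.JNa_g;
    ts(nrow_ts, j++) = f.JK_g;
    ts(nrow_ts, j++) = f.JA_g;
    ts(nrow_ts, j++) = f.JCa_g;
    ts(nrow_ts, j++) = f.JNa_z;
    ts(nrow_ts, j++) = f.JK_z;
    ts(nrow_ts, j++) = f.JA_z;
    ts(nrow_ts, j++) = f.JCa_z;
    ts(nrow_ts, j++) = f.JMg_z;
    ts(nrow_ts, j++) = kind;
    ts(nrow_ts, j++) = open ? amp : 0.0;
    ++nrow_ts;
  };

  for (int i = 0; i < ntr; ++i) {
    double kind = schedule(i, 0);
    double dur = schedule(i, 1);
    double amp = schedule(i, 2);
    bool deoxy = kind > 0.5;
    bool open = deoxy;

    // transit boundary: switch oxygenation, re-equilibrate
    s[S_oxy] = deoxy ? 0.0 : 1.0;
    equilibrate_c(s, p.data(), amp, open);

    // accumulators for per-transit statistics
    double w = 0.0, a_rv = 0.0, a_ph = 0.0, mn_ph = 1e9, a_em = 0.0;
    double a_cna = 0.0, a_ck = 0.0, a_ca = 0.0, a_mgt = 0.0, a_mgf = 0.0;
    double a_caf = 0.0, mn_jp = 1e9, mx_jp = -1e9, a_jp = 0.0, a_jcp = 0.0;
    double a_jg = 0.0, a_jpass = 0.0, a_hbo = 0.0;

    double done = 0.0;
    while (done < dur - 1e-9) {
      double dt = std::min(dt_s, dur - done);
      // events (pump inhibition, parameter changes) fire between steps
      while (ev_i < nev && events(ev_order[ev_i], 0) * 3600.0 <= t_s + 1e-9) {
        int k = ev_order[ev_i];
        int pi = (int)events(k, 1);
        if (pi < 0 || pi >= NPAR) stop("event parameter index out of range");
        p[pi] = events(k, 2);
        equilibrate_c(s, p.data(), amp, open);
        record_row(amp, open, kind);
        ++ev_i;
      }
      Fluxes f;
      step_c(s, p.data(), dt, amp, open, &f);
      t_s += dt;
      done += dt;

      double Vw = s[S_Vw];
      double hw = dt;
      w += hw;
      a_rv += hw * (Vw + Vsolid);
      a_ph += hw * s[S_pHi];
      if (s[S_pHi] < mn_ph) mn_ph = s[S_pHi];
      a_em += hw * s[S_Em];
      a_cna += hw * s[S_QNa] / Vw;
      a_ck += hw * s[S_QK] / Vw;
      a_ca += hw * s[S_QA] / Vw;
      a_mgt += hw * s[S_QMgT] / Vw;
      a_mgf += hw * s[S_MgF];
      a_caf += hw * s[S_CaF];
      double jp = f.JNa_p;
      if (jp < mn_jp) mn_jp = jp;
      if (jp > mx_jp) mx_jp = jp;
      a_jp += hw * jp;
      a_jcp += hw * f.JCa_p;
      a_jg += hw * f.JK_gard;
      a_jpass += hw * (f.JNa_g + f.JNa_z);
      double CHb = p[P_QHb] / Vw;
      a_hbo += hw * fhb_c(CHb, p[P_b1], p[P_b2]) * CHb;

      if (t_s + 1e-9 >= next_record) {
        record_row(amp, open, kind);
        next_record += record_s;
      }
    }
    // boundary record at transit end
    record_row(amp, open, kind);

    int j = 0;
    tr(i, j++) = i + 1;
    tr(i, j++) = kind;
    tr(i, j++) = (t_s - dur) / 3600.0;
    tr(i, j++) = t_s / 3600.0;
    tr(i, j++) = dur;
    tr(i, j++) = open ? amp : 0.0;
    tr(i, j++) = a_rv / w;
    tr(i, j++) = a_ph / w;
    tr(i, j++) = mn_ph;
    tr(i, j++) = a_em / w;
    tr(i, j++) = a_cna / w;
    tr(i, j++) = a_ck / w;
    tr(i, j++) = a_ca / w;
    tr(i, j++) = a_mgt / w;
    tr(i, j++) = a_mgf / w;
    tr(i, j++) = a_caf / w;
    tr(i, j++) = mn_jp;
    tr(i, j++) = mx_jp;
    tr(i, j++) = a_jp / w;
    tr(i, j++) = a_jcp / w;
    tr(i, j++) = a_jg / w;
    tr(i, j++) = a_jpass / w;
    tr(i, j++) = a_hbo / w;
  }

  NumericMatrix ts_out(nrow_ts, NTS);
  for (int c = 0; c < NTS; ++c)
    for (int r = 0; r < nrow_ts; ++r) ts_out(r, c) = ts(r, c);
  CharacterVector tsn(NTS), trn(NTR);
  for (int c = 0; c < NTS; ++c) tsn[c] = TS_COLS[c];
  for (int c = 0; c < NTR; ++c) trn[c] = TR_COLS[c];
  colnames(ts_out) = tsn;
  colnames(tr) = trn;

  NumericVector sfin(NSTATE);
  std::copy(s, s + NSTATE, sfin.begin());
  return List::create(_["ts"] = ts_out, _["transits"] = tr,
                      _["final_state"] = sfin);
}
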