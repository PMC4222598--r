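// TP06 human ventricular epicardial cell model with an ATP-sensitive potassium
// current, plus explicit-Euler monodomain drivers for single cells, 1D cables
// and 2D sheets.  Gating variables use Rush-Larsen exponential integration;
// voltage-only rate functions may be served from pre-computed look-up tables.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---- physical constants (TP06 units) --------------------------------------
static const double Rgas = 8314.472;      // J/(kmol K)
static const double Frd  = 96485.3415;    // C/mol
static const double Temp = 310.0;         // K
static const double RTONF = Rgas * Temp / Frd;   // mV
static const double CAP  = 0.185;         // cell capacitance scaling (uF)
static const double Vc   = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Nao  = 140.0, Cao = 2.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncxgam = 0.35,
                    ncxalpha = 2.5;
static const double pKNa = 0.03, KmK = 1.0, KmNa = 40.0;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0,
                    Vleak = 0.00036, Vxfer = 0.0038;
static const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
                    Bufss = 0.4, Kbufss = 0.00025;
static const double KpCa = 0.0005;
static const double KO_BASE = 5.4;

// state vector layout (19 variables per node)
enum { iV = 0, im, ih, ij, id, iff, if2, ifcass, ir, is_, ixr1, ixr2, ixs,
       iNai, iKi, iCai, iCaSS, iCaSR, iRbar, NSTATE };

struct Pars {
  double GNa, GK1, Gto, GKr, GKs, GCaL, GbNa, GbCa, GpK, GpCa, PNaK, kNaCa;
  double taufmult;   // tau_f multiplier applied for V > 0 (slope presets)
  double g0katp;     // I_KATP scaling coefficient (per percent open fraction)
};

struct Isch { double Ko, acid, fatp; };  // fatp in percent

static Pars parsFromList(List p) {
  Pars q;
  q.GNa = p["GNa"]; q.GK1 = p["GK1"]; q.Gto = p["Gto"]; q.GKr = p["GKr"];
  q.GKs = p["GKs"]; q.GCaL = p["GCaL"]; q.GbNa = p["GbNa"];
  q.GbCa = p["GbCa"]; q.GpK = p["GpK"]; q.GpCa = p["GpCa"];
  q.PNaK = p["PNaK"]; q.kNaCa = p["kNaCa"]; q.taufmult = p["taufmult"];
  q.g0katp = p["g0katp"];
  return q;
}
static Isch ischFromList(List s) {
  Isch i; i.Ko = s["Ko"]; i.acid = s["acidosis"]; i.fatp = s["f_atp"];
  return i;
}

// ---- voltage-dependent rate functions (inf, tau) --------------------------
static inline void rate_m(double V, double &inf, double &tau) {
  inf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2);
  double a = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double b = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
             0.1 / (1.0 + exp((V - 50.0) / 200.0));
  tau = a * b;
}
static inline void rate_h(double V, double &inf, double &tau) {
  inf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2);
  double a, b;
  if (V < -40.0) {
    a = 0.057 * exp(-(V + 80.0) / 6.8);
    b = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
  } else {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
  }
  tau = 1.0 / (a + b);
}
static inline void rate_j(double V, double &inf, double &tau) {
  inf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2);
  double a, b;
  if (V < -40.0) {
    a = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    b = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  } else {
    a = 0.0;
    b = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  }
  tau = 1.0 / (a + b);
}
static inline void rate_d(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double a = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double b = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  tau = a * b + c;
}
static inline void rate_f(double V, double taufmult, double &inf, double &tau) {
  inf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
        200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
        180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  if (V > 0.0) tau *= taufmult;
}
static inline void rate_f2(double V, double &inf, double &tau) {
  inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  tau = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
        31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
        80.0 / (1.0 + exp((V + 30.0) / 10.0));
}
static inline void rate_r(double V, double &inf, double &tau) {  // epicardial
  inf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
}
static inline void rate_s(double V, double &inf, double &tau) {  // epicardial
  inf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
        5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
}
static inline void rate_xr1(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  tau = a * b;
}
static inline void rate_xr2(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  tau = a * b;
}
static inline void rate_xs(double V, double &inf, double &tau) {
  inf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  tau = a * b + 80.0;
}

// voltage-only current factors
static inline void ical_factors(double V, double &c1, double &c2) {
  // ICaL = GCaL*d*f*f2*fCass*(c1*CaSS - c2)
  double z = 2.0 * (V - 15.0) * Frd / (Rgas * Temp);
  double A = 4.0 * (V - 15.0) * Frd * Frd / (Rgas * Temp);
  if (fabs(z) < 1e-7) {
    // limit V -> 15 mV: A = 2*F*z, (e^z - 1) -> z, e^z -> 1
    c1 = 0.5 * Frd;
    c2 = 2.0 * Frd * Cao;
    return;
  }
  double e = exp(z);
  c1 = A * 0.25 * e / (e - 1.0);
  c2 = A * Cao / (e - 1.0);
}
static inline double xk1_inf(double u) {  // u = V - EK
  double a = 0.1 / (1.0 + exp(0.06 * (u - 200.0)));
  double b = (3.0 * exp(0.0002 * (u + 100.0)) + exp(0.1 * (u - 10.0))) /
             (1.0 + exp(-0.5 * u));
  return a / (a + b);
}
static inline void ncx_factors(double V, double &n1, double &n2) {
  // INaCa = kNaCa*(n1*Nai^3 - n2*Cai) -- kNaCa folded in by caller
  double e1 = exp(ncxgam * V / RTONF);
  double e2 = exp((ncxgam - 1.0) * V / RTONF);
  double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
               (1.0 + ksat * e2);
  n1 = e1 * Cao / den;
  n2 = e2 * Nao * Nao * Nao * ncxalpha / den;
}
static inline double inak_factor(double V) {
  return 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTONF) +
                0.0353 * exp(-V / RTONF));
}
static inline double ipk_factor(double V) {
  return 1.0 / (1.0 + exp((25.0 - V) / 5.98));
}
static inline double ikatp_factor(double V) {
  // voltage factor of the ATP-sensitive potassium current
  return 1.0 / (40.0 + 3.5 * exp(0.025 * V));
}

// ---- look-up tables --------------------------------------------------------
// 29 voltage-indexed entries per grid point, interleaved so one node-step
// touches two contiguous rows; xK1 is tabulated separately against V - EK.
static const int NTAB = 29;
static const double LUT_VMIN = -100.0, LUT_VMAX = 70.0;
static const double XK1_UMIN = -150.0, XK1_UMAX = 320.0;

struct Lut {
  double step, inv, vmin;
  int nv;
  std::vector<double> tab;     // nv * NTAB
  double ustep, uinv, umin;
  int nu;
  std::vector<double> xk1;
  double dt, taufmult;
  bool valid;
  Lut() : valid(false) {}
};

static Lut g_lut;  // rebuilt whenever dt / taufmult / step change

static void build_lut(double dt, double taufmult, double step) {
  Lut &L = g_lut;
  L.step = step; L.inv = 1.0 / step; L.vmin = LUT_VMIN;
  L.nv = (int)floor((LUT_VMAX - LUT_VMIN) / step) + 2;
  L.tab.assign((size_t)L.nv * NTAB, 0.0);
  double inf, tau;
  for (int k = 0; k < L.nv; ++k) {
    double V = LUT_VMIN + k * step;
    double *row = &L.tab[(size_t)k * NTAB];
    rate_m(V, inf, tau);  row[0] = inf;  row[1] = exp(-dt / tau);
    rate_h(V, inf, tau);  row[2] = inf;  row[3] = exp(-dt / tau);
    rate_j(V, inf, tau);  row[4] = inf;  row[5] = exp(-dt / tau);
    rate_d(V, inf, tau);  row[6] = inf;  row[7] = exp(-dt / tau);
    rate_f(V, taufmult, inf, tau); row[8] = inf;  row[9] = exp(-dt / tau);
    rate_f2(V, inf, tau); row[10] = inf; row[11] = exp(-dt / tau);
    rate_r(V, inf, tau);  row[12] = inf; row[13] = exp(-dt / tau);
    rate_s(V, inf, tau);  row[14] = inf; row[15] = exp(-dt / tau);
    rate_xr1(V, inf, tau); row[16] = inf; row[17] = exp(-dt / tau);
    rate_xr2(V, inf, tau); row[18] = inf; row[19] = exp(-dt / tau);
    rate_xs(V, inf, tau); row[20] = inf; row[21] = exp(-dt / tau);
    double c1, c2; ical_factors(V, c1, c2); row[22] = c1; row[23] = c2;
    double n1, n2; ncx_factors(V, n1, n2); row[24] = n1; row[25] = n2;
    row[26] = inak_factor(V);
    row[27] = ipk_factor(V);
    row[28] = ikatp_factor(V);
  }
  L.ustep = step; L.uinv = 1.0 / step; L.umin = XK1_UMIN;
  L.nu = (int)floor((XK1_UMAX - XK1_UMIN) / step) + 2;
  L.xk1.assign(L.nu, 0.0);
  for (int k = 0; k < L.nu; ++k) L.xk1[k] = xk1_inf(XK1_UMIN + k * step);
  L.dt = dt; L.taufmult = taufmult; L.valid = true;
}

static inline void ensure_lut(double dt, double taufmult, double step) {
  if (!g_lut.valid || g_lut.dt != dt || g_lut.taufmult != taufmult ||
      g_lut.step != step)
    build_lut(dt, taufmult, step);
}

// ---- single node update ----------------------------------------------------
struct Globals {
  // per-step effective quantities shared by all nodes
  double gNaEff, gCaLEff, sqKo, katpScale, Ko;
  double dt;
  bool use_lut;
  double taufmult;
};

struct ECache { double EK, ENa, EKs, ECa; };

static inline void refresh_E(const double *s, double Ko, ECache &E) {
  E.EK  = RTONF * log(Ko / s[iKi]);
  E.ENa = RTONF * log(Nao / s[iNai]);
  E.EKs = RTONF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  E.ECa = 0.5 * RTONF * log(Cao / s[iCai]);
}

// advance one node one step; returns new V (also written into s[iV]);
// s has NSTATE doubles.  lap is the diffusion contribution in mV/ms.
static inline double step_node(double *s, double Istim, double lap,
                               const Pars &P, const Globals &G,
                               const ECache &E) {
  const double V = s[iV];
  double vals[NTAB];
  if (G.use_lut) {
    double x = (V - g_lut.vmin) * g_lut.inv;
    int k = (int)x;
    if (k < 0) { k = 0; x = 0.0; }
    if (k >= g_lut.nv - 1) { k = g_lut.nv - 2; x = (double)(g_lut.nv - 1); }
    double fr = x - k;
    const double *r0 = &g_lut.tab[(size_t)k * NTAB];
    const double *r1 = r0 + NTAB;
    for (int t = 0; t < NTAB; ++t) vals[t] = r0[t] + fr * (r1[t] - r0[t]);
  } else {
    double inf, tau;
    rate_m(V, inf, tau);  vals[0] = inf;  vals[1] = exp(-G.dt / tau);
    rate_h(V, inf, tau);  vals[2] = inf;  vals[3] = exp(-G.dt / tau);
    rate_j(V, inf, tau);  vals[4] = inf;  vals[5] = exp(-G.dt / tau);
    rate_d(V, inf, tau);  vals[6] = inf;  vals[7] = exp(-G.dt / tau);
    rate_f(V, G.taufmult, inf, tau); vals[8] = inf; vals[9] = exp(-G.dt / tau);
    rate_f2(V, inf, tau); vals[10] = inf; vals[11] = exp(-G.dt / tau);
    rate_r(V, inf, tau);  vals[12] = inf; vals[13] = exp(-G.dt / tau);
    rate_s(V, inf, tau);  vals[14] = inf; vals[15] = exp(-G.dt / tau);
    rate_xr1(V, inf, tau); vals[16] = inf; vals[17] = exp(-G.dt / tau);
    rate_xr2(V, inf, tau); vals[18] = inf; vals[19] = exp(-G.dt / tau);
    rate_xs(V, inf, tau); vals[20] = inf; vals[21] = exp(-G.dt / tau);
    double c1, c2; ical_factors(V, c1, c2); vals[22] = c1; vals[23] = c2;
    double n1, n2; ncx_factors(V, n1, n2); vals[24] = n1; vals[25] = n2;
    vals[26] = inak_factor(V);
    vals[27] = ipk_factor(V);
    vals[28] = ikatp_factor(V);
  }

  const double u = V - E.EK;
  double xk1;
  if (G.use_lut) {
    double x = (u - g_lut.umin) * g_lut.uinv;
    int k = (int)x;
    if (k < 0) { k = 0; x = 0.0; }
    if (k >= g_lut.nu - 1) { k = g_lut.nu - 2; x = (double)(g_lut.nu - 1); }
    double fr = x - k;
    xk1 = g_lut.xk1[k] + fr * (g_lut.xk1[k + 1] - g_lut.xk1[k]);
  } else {
    xk1 = xk1_inf(u);
  }

  const double Nai = s[iNai], Ki = s[iKi], Cai = s[iCai], CaSS = s[iCaSS],
               CaSR = s[iCaSR];

  const double INa  = G.gNaEff * s[im] * s[im] * s[im] * s[ih] * s[ij] *
                      (V - E.ENa);
  const double ICaL = G.gCaLEff * s[id] * s[iff] * s[if2] * s[ifcass] *
                      (vals[22] * CaSS - vals[23]);
  const double Ito  = P.Gto * s[ir] * s[is_] * u;
  const double IKr  = P.GKr * G.sqKo * s[ixr1] * s[ixr2] * u;
  const double IKs  = P.GKs * s[ixs] * s[ixs] * (V - E.EKs);
  const double IK1  = P.GK1 * G.sqKo * xk1 * u;
  const double INaCa = P.kNaCa * (vals[24] * Nai * Nai * Nai - vals[25] * Cai);
  const double INaK = P.PNaK * G.Ko / (G.Ko + KmK) * Nai / (Nai + KmNa) *
                      vals[26];
  const double IpCa = P.GpCa * Cai / (Cai + KpCa);
  const double IpK  = P.GpK * vals[27] * u;
  const double IbNa = P.GbNa * (V - E.ENa);
  const double IbCa = P.GbCa * (V - E.ECa);
  const double IKatp = G.katpScale * vals[28] * u;

  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK +
                      IpCa + IpK + IbNa + IbCa + IKatp;

  // --- calcium subsystem ---
  const double kCaSR = maxsr - (maxsr - minsr) /
                       (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kCaSR;
  const double k2 = k2p * kCaSR;
  const double O = k1 * CaSS * CaSS * s[iRbar] /
                   (k3 + k1 * CaSS * CaSS);
  const double Irel  = Vrel * O * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup   = Vmaxup / (1.0 + (Kup / Cai) * (Kup / Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  s[iRbar] += G.dt * (k4 * (1.0 - s[iRbar]) - k2 * CaSS * s[iRbar]);

  { // CaSR with instantaneous CSQN buffering
    const double buf = Bufsr * CaSR / (CaSR + Kbufsr);
    const double d = G.dt * (Iup - Irel - Ileak);
    const double b = Bufsr - buf - d - CaSR + Kbufsr;
    const double c = Kbufsr * (buf + d + CaSR);
    s[iCaSR] = (sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  { // subspace calcium
    const double buf = Bufss * CaSS / (CaSS + Kbufss);
    const double d = G.dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                             (-ICaL * CAP / (2.0 * Vss * Frd)));
    const double b = Bufss - buf - d - CaSS + Kbufss;
    const double c = Kbufss * (buf + d + CaSS);
    s[iCaSS] = (sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  { // cytosolic calcium
    const double buf = Bufc * Cai / (Cai + Kbufc);
    const double d = G.dt * (-(IbCa + IpCa - 2.0 * INaCa) * CAP /
                             (2.0 * Vc * Frd) -
                             (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double b = Bufc - buf - d - Cai + Kbufc;
    const double c = Kbufc * (buf + d + Cai);
    s[iCai] = (sqrt(b * b + 4.0 * c) - b) / 2.0;
  }

  s[iNai] += -G.dt * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * CAP /
             (Vc * Frd);
  s[iKi]  += -G.dt * (Istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK +
                      IKatp) * CAP / (Vc * Frd);

  // --- Rush-Larsen gate updates (voltage gates) ---
  s[im]   = vals[0]  - (vals[0]  - s[im])   * vals[1];
  s[ih]   = vals[2]  - (vals[2]  - s[ih])   * vals[3];
  s[ij]   = vals[4]  - (vals[4]  - s[ij])   * vals[5];
  s[id]   = vals[6]  - (vals[6]  - s[id])   * vals[7];
  s[iff]  = vals[8]  - (vals[8]  - s[iff])  * vals[9];
  s[if2]  = vals[10] - (vals[10] - s[if2])  * vals[11];
  s[ir]   = vals[12] - (vals[12] - s[ir])   * vals[13];
  s[is_]  = vals[14] - (vals[14] - s[is_])  * vals[15];
  s[ixr1] = vals[16] - (vals[16] - s[ixr1]) * vals[17];
  s[ixr2] = vals[18] - (vals[18] - s[ixr2]) * vals[19];
  s[ixs]  = vals[20] - (vals[20] - s[ixs])  * vals[21];
  { // fCass gate depends on CaSS only; forward Euler (tau >= 2 ms >> dt)
    const double x = (CaSS / 0.05) * (CaSS / 0.05);
    const double inf = 0.6 / (1.0 + x) + 0.4;
    const double tau = 80.0 / (1.0 + x) + 2.0;
    s[ifcass] += G.dt * (inf - s[ifcass]) / tau;
  }

  const double Vnew = V + G.dt * (-(Iion + Istim) + lap);
  s[iV] = Vnew;
  return Vnew;
}

static inline Globals make_globals(const Pars &P, const Isch &S, double dt,
                                   bool use_lut) {
  Globals G;
  G.gNaEff = P.GNa * S.acid;
  G.gCaLEff = P.GCaL * S.acid;
  G.sqKo = sqrt(S.Ko / KO_BASE);
  G.katpScale = P.g0katp * S.fatp * pow(S.Ko / KO_BASE, 0.3);
  G.Ko = S.Ko;
  G.dt = dt;
  G.use_lut = use_lut;
  G.taufmult = P.taufmult;
  return G;
}

// ---- exported: current decomposition at a state ----------------------------
// [[Rcpp::export]]
List ionic_currents_cpp(NumericVector state, List pars, List isch) {
  Pars P = parsFromList(pars);
  Isch S = ischFromList(isch);
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state[k];
  ECache E; refresh_E(s, S.Ko, E);
  const double V = s[iV];
  double c1, c2, n1, n2;
  ical_factors(V, c1, c2);
  ncx_factors(V, n1, n2);
  const double u = V - E.EK;
  const double gNaEff = P.GNa * S.acid, gCaLEff = P.GCaL * S.acid;
  const double sqKo = sqrt(S.Ko / KO_BASE);
  const double katpScale = P.g0katp * S.fatp * pow(S.Ko / KO_BASE, 0.3);
  const double INa = gNaEff * s[im] * s[im] * s[im] * s[ih] * s[ij] *
                     (V - E.ENa);
  const double ICaL = gCaLEff * s[id] * s[iff] * s[if2] * s[ifcass] *
                      (c1 * s[iCaSS] - c2);
  const double Ito = P.Gto * s[ir] * s[is_] * u;
  const double IKr = P.GKr * sqKo * s[ixr1] * s[ixr2] * u;
  const double IKs = P.GKs * s[ixs] * s[ixs] * (V - E.EKs);
  const double IK1 = P.GK1 * sqKo * xk1_inf(u) * u;
  const double INaCa = P.kNaCa * (n1 * s[iNai] * s[iNai] * s[iNai] -
                                  n2 * s[iCai]);
  const double INaK = P.PNaK * S.Ko / (S.Ko + KmK) * s[iNai] /
                      (s[iNai] + KmNa) * inak_factor(V);
  const double IpCa = P.GpCa * s[iCai] / (s[iCai] + KpCa);
  const double IpK = P.GpK * ipk_factor(V) * u;
  const double IbNa = P.GbNa * (V - E.ENa);
  const double IbCa = P.GbCa * (V - E.ECa);
  const double IKatp = katpScale * ikatp_factor(V) * u;
  const double tot = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK +
                     IpCa + IpK + IbNa + IbCa + IKatp;
  return List::create(
      _["INa"] = INa, _["ICaL"] = ICaL, _["Ito"] = Ito, _["IKr"] = IKr,
      _["IKs"] = IKs, _["IK1"] = IK1, _["INaCa"] = INaCa, _["INaK"] = INaK,
      _["IpCa"] = IpCa, _["IpK"] = IpK, _["IbNa"] = IbNa, _["IbCa"] = IbCa,
      _["IKatp"] = IKatp, _["total"] = tot, _["EK"] = E.EK);
}

static void check_state_ok(const double *s, double Vold, double guard,
                           double t, int node, double dt) {
  if (!R_finite(s[iV]))
    stop("integration instability: non-finite V at t = %.3f ms, node %d "
         "(dt = %g ms)", t, node + 1, dt);
  if (fabs(s[iV] - Vold) > guard)
    stop("integration instability: |dV| = %.2f mV in one step at t = %.3f ms,"
         " node %d (dt = %g ms)", fabs(s[iV] - Vold), t, node + 1, dt);
}

// ---- exported: single-cell driver ------------------------------------------
// stim_onsets in ms; records V every record_dt; returns final state.
// [[Rcpp::export]]
List run_cell_cpp(NumericVector state0, List pars, List isch, double dt,
                  double duration, NumericVector stim_onsets,
                  double stim_dur, double stim_amp, double record_dt,
                  bool use_lut = true, double lut_step = 0.01,
                  int e_refresh = 10, double guard = 10.0) {
  Pars P = parsFromList(pars);
  Isch S = ischFromList(isch);
  if (use_lut) ensure_lut(dt, P.taufmult, lut_step);
  Globals G = make_globals(P, S, dt, use_lut);
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k];
  ECache E; refresh_E(s, S.Ko, E);

  const long nstep = (long)llround(duration / dt);
  const int rec_every = std::max(1, (int)llround(record_dt / dt));
  const long nrec = nstep / rec_every + 1;
  NumericVector tout(nrec), Vout(nrec);
  long ri = 0;
  tout[ri] = 0.0; Vout[ri] = s[iV]; ++ri;

  // stimulus schedule
  int nstim = stim_onsets.size(), sp = 0;
  int rec_ctr = rec_every, e_ctr = 0;

  for (long it = 0; it < nstep; ++it) {
    const double t = it * dt;
    double Istim = 0.0;
    while (sp < nstim && t >= stim_onsets[sp] + stim_dur) ++sp;
    if (sp < nstim && t >= stim_onsets[sp] && t < stim_onsets[sp] + stim_dur)
      Istim = stim_amp;
    if (e_ctr-- == 0) { refresh_E(s, S.Ko, E); e_ctr = e_refresh - 1; }
    const double Vold = s[iV];
    step_node(s, Istim, 0.0, P, G, E);
    check_state_ok(s, Vold, guard, t, 0, dt);
    if (--rec_ctr == 0) {
      rec_ctr = rec_every;
      if (ri < nrec) {
        tout[ri] = (it + 1) * dt;
        Vout[ri] = s[iV];
        ++ri;
      }
    }
  }
  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = s[k];
  return List::create(_["t"] = tout[Range(0, ri - 1)],
                      _["V"] = Vout[Range(0, ri - 1)],
                      _["state"] = fin);
}

// single (or n) explicit step(s) for one cell; used by step_cell()
// [[Rcpp::export]]
NumericVector step_cell_cpp(NumericVector state, double Istim, double dt,
                            List pars, List isch, int nsteps = 1,
                            bool use_lut = false, double lut_step = 0.01,
                            double guard = 10.0) {
  Pars P = parsFromList(pars);
  Isch S = ischFromList(isch);
  if (use_lut) ensure_lut(dt, P.taufmult, lut_step);
  Globals G = make_globals(P, S, dt, use_lut);
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state[k];
  ECache E;
  for (int it = 0; it < nsteps; ++it) {
    refresh_E(s, S.Ko, E);
    const double Vold = s[iV];
    step_node(s, Istim, 0.0, P, G, E);
    check_state_ok(s, Vold, guard, it * dt, 0, dt);
  }
  NumericVector out(NSTATE);
  for (int k = 0; k < NSTATE; ++k) out[k] = s[k];
  return out;
}

// ---- diffusion term (exported for direct testing) ---------------------------
// 3-point (ny = 1) or 5-point Laplacian with no-flux boundaries via
// cell-centred mirror ghosts; D in cm^2/ms, dx in cm; result in mV/ms.
static void laplacian(const std::vector<double> &V, int nx, int ny,
                      double DoDx2, std::vector<double> &lap) {
  for (int j = 0; j < ny; ++j) {
    const int off = j * nx;
    const int offN = (j > 0 ? j - 1 : j) * nx;
    const int offS = (j < ny - 1 ? j + 1 : j) * nx;
    for (int i = 0; i < nx; ++i) {
      const double v = V[off + i];
      const double vw = V[off + (i > 0 ? i - 1 : i)];
      const double ve = V[off + (i < nx - 1 ? i + 1 : i)];
      double acc = vw + ve - 2.0 * v;
      if (ny > 1) acc += V[offN + i] + V[offS + i] - 2.0 * v;
      lap[off + i] = DoDx2 * acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector diffusion_term_cpp(NumericVector Vfield, int nx, int ny,
                                 double D, double dx) {
  std::vector<double> V(Vfield.begin(), Vfield.end());
  std::vector<double> lap(V.size());
  laplacian(V, nx, ny, D / (dx * dx), lap);
  return NumericVector(lap.begin(), lap.end());
}

// ---- tissue driver ----------------------------------------------------------
// states: nnode x NSTATE matrix (column-major, node fastest).
// stimuli: columns onset, dur, amp, ix0, ix1, iy0, iy1 (1-based inclusive).
// ramp: if ramp_t1 > ramp_t0, ischemia parameters are interpolated linearly
// from isch (at t <= ramp_t0) to isch_to (at t >= ramp_t1).
// [[Rcpp::export]]
List run_tissue_cpp(NumericMatrix states, int nx, int ny, List pars,
                    List isch, List isch_to, double ramp_t0, double ramp_t1,
                    double D, double dx, double dt, double t0,
                    double duration, DataFrame stimuli,
                    IntegerVector probes, double probe_dt, double snap_dt,
                    bool use_lut = true, double lut_step = 0.01,
                    int e_refresh = 10, double guard = 10.0,
                    bool record_final = true) {
  const int nnode = nx * ny;
  if (states.nrow() != nnode || states.ncol() != NSTATE)
    stop("states must be a (nx*ny) x %d matrix", NSTATE);
  Pars P = parsFromList(pars);
  Isch S0 = ischFromList(isch);
  Isch S1 = ischFromList(isch_to);
  const bool ramp = ramp_t1 > ramp_t0;

  // diffusion stability (explicit Euler)
  const int dim = ny > 1 ? 2 : 1;
  if (D > 0 && dt >= dx * dx / (2.0 * dim * D))
    stop("diffusion stability violated: need dt < dx^2/(2*d*D) = %g ms",
         dx * dx / (2.0 * dim * D));
  if (use_lut) ensure_lut(dt, P.taufmult, lut_step);

  // node-major state: node n occupies st[n*NSTATE .. n*NSTATE+18]
  std::vector<double> st((size_t)nnode * NSTATE);
  for (int k = 0; k < NSTATE; ++k)
    for (int n = 0; n < nnode; ++n) st[(size_t)n * NSTATE + k] = states(n, k);

  std::vector<ECache> E(nnode);
  std::vector<double> lap(nnode, 0.0), vbuf(nnode);

  NumericVector s_on = stimuli["onset"], s_dur = stimuli["duration"],
                s_amp = stimuli["amplitude"];
  IntegerVector s_x0 = stimuli["ix0"], s_x1 = stimuli["ix1"],
                s_y0 = stimuli["iy0"], s_y1 = stimuli["iy1"];
  const int nstim = s_on.size();

  const long nstep = (long)llround(duration / dt);
  const int prec = probe_dt > 0 ? std::max(1, (int)llround(probe_dt / dt)) : 0;
  const int srec = snap_dt > 0 ? std::max(1, (int)llround(snap_dt / dt)) : 0;
  const int nprobe = probes.size();
  const long nprec = prec > 0 ? nstep / prec + 1 : 0;
  const long nsrec = srec > 0 ? nstep / srec + 1 : 0;

  NumericMatrix probeV(std::max(nprec, 1L), std::max(nprobe, 1));
  NumericVector probeT(std::max(nprec, 1L));
  NumericMatrix snaps(nsrec > 0 ? nnode : 1, std::max(nsrec, 1L));
  NumericVector snapT(std::max(nsrec, 1L));
  long pi = 0, si = 0;

  if (prec > 0) {
    probeT[pi] = t0;
    for (int q = 0; q < nprobe; ++q)
      probeV(pi, q) = st[(size_t)(probes[q] - 1) * NSTATE + iV];
    ++pi;
  }
  if (srec > 0) {
    snapT[si] = t0;
    for (int n = 0; n < nnode; ++n) snaps(n, si) = st[(size_t)n * NSTATE + iV];
    ++si;
  }

  const double DoDx2 = D / (dx * dx);
  int e_ctr = 0, p_ctr = prec, s_ctr = srec, ui_ctr = 20000;

  for (long it = 0; it < nstep; ++it) {
    const double t = t0 + it * dt;

    // time-varying ischemia (linear ramp)
    Isch S = S0;
    if (ramp) {
      double w = (t - ramp_t0) / (ramp_t1 - ramp_t0);
      if (w < 0) w = 0;
      if (w > 1) w = 1;
      S.Ko = S0.Ko + w * (S1.Ko - S0.Ko);
      S.acid = S0.acid + w * (S1.acid - S0.acid);
      S.fatp = S0.fatp + w * (S1.fatp - S0.fatp);
    }
    Globals G = make_globals(P, S, dt, use_lut);

    if (D > 0) {
      for (int n = 0; n < nnode; ++n) vbuf[n] = st[(size_t)n * NSTATE + iV];
      laplacian(vbuf, nx, ny, DoDx2, lap);
    }

    // active stimuli this step
    int act[8]; int nact = 0;
    for (int q = 0; q < nstim && nact < 8; ++q)
      if (t >= s_on[q] && t < s_on[q] + s_dur[q]) act[nact++] = q;

    const bool refresh = (e_ctr-- == 0);
    if (refresh) e_ctr = e_refresh - 1;
    double *sp_ = &st[0];
    for (int n = 0; n < nnode; ++n, sp_ += NSTATE) {
      if (refresh) refresh_E(sp_, S.Ko, E[n]);
      double Istim = 0.0;
      if (nact) {
        const int ix = n % nx + 1, iy = n / nx + 1;
        for (int a = 0; a < nact; ++a) {
          const int q = act[a];
          if (ix >= s_x0[q] && ix <= s_x1[q] && iy >= s_y0[q] &&
              iy <= s_y1[q])
            Istim += s_amp[q];
        }
      }
      const double Vold = sp_[iV];
      step_node(sp_, Istim, D > 0 ? lap[n] : 0.0, P, G, E[n]);
      if (!R_finite(sp_[iV]) || fabs(sp_[iV] - Vold) > guard) {
        const int ix = n % nx + 1, iy = n / nx + 1;
        stop("integration instability at t = %.3f ms, node (%d, %d): "
             "|dV| step = %g mV (dt = %g ms)", t, ix, iy,
             fabs(sp_[iV] - Vold), dt);
      }
    }

    if (prec > 0 && --p_ctr == 0) {
      p_ctr = prec;
      if (pi < nprec) {
        probeT[pi] = t0 + (it + 1) * dt;
        for (int q = 0; q < nprobe; ++q)
          probeV(pi, q) = st[(size_t)(probes[q] - 1) * NSTATE + iV];
        ++pi;
      }
    }
    if (srec > 0 && --s_ctr == 0) {
      s_ctr = srec;
      if (si < nsrec) {
        snapT[si] = t0 + (it + 1) * dt;
        for (int n = 0; n < nnode; ++n)
          snaps(n, si) = st[(size_t)n * NSTATE + iV];
        ++si;
      }
    }
    if (--ui_ctr == 0) { ui_ctr = 20000; Rcpp::checkUserInterrupt(); }
  }

  List out = List::create(
      _["probe_t"] = prec > 0 ? probeT[Range(0, pi - 1)] : NumericVector(0),
      _["probe_V"] = probeV,
      _["n_probe_rec"] = (double)pi,
      _["snap_t"] = srec > 0 ? snapT[Range(0, si - 1)] : NumericVector(0),
      _["snaps"] = snaps,
      _["n_snap_rec"] = (double)si,
      _["t_end"] = t0 + nstep * dt);
  if (record_final) {
    NumericMatrix fin(nnode, NSTATE);
    for (int k = 0; k < NSTATE; ++k)
      for (int n = 0; n < nnode; ++n) fin(n, k) = st[(size_t)n * NSTATE + k];
    out["states"] = fin;
  }
  return out;
}

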