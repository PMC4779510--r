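// Ionic cell models and monodomain tissue stepping.
//
// Cell models: ten Tusscher & Panfilov (2006) human ventricular myocyte
// (endocardial / mid-myocardial / epicardial variants) and Stewart et al.
// (2009) Purkinje fibre cell. All parameters are the published values; the
// maximal IK1 conductance g_k1 is exposed as a runtime override.
//
// Numerics: Rush-Larsen exponential updates for gating variables, forward
// Euler for the membrane potential and ion concentrations, analytic
// steady-state buffering for the calcium compartments (as in the published
// reference code of the ventricular model). Voltage-dependent rate
// quantities are tabulated on a 0.05 mV grid with linear interpolation
// (rebuilt whenever dt changes); an untabulated path evaluating the closed
// forms is kept for cross-checking.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <memory>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// state layout (20 doubles per cell)
enum StateIdx {
  SV = 0, SKI, SNAI, SCAI, SCASS, SCASR, SRR,
  SM, SH, SJ, SXR1, SXR2, SXS, SR, SS, SD, SF, SF2, SFCASS, SY
};
static const int NSTATE = 20;

// cell type codes (match R side)
static const int CT_ENDO = 1, CT_MID = 2, CT_EPI = 3, CT_PURK = 4;

// ---------------------------------------------------------------------------
// physical constants and shared model parameters
static const double Rgas = 8314.472;      // mJ/(mol K)
static const double Frdy = 96485.3415;    // C/mol
static const double Temp = 310.0;         // K
static const double RTONF = Rgas * Temp / Frdy; // mV
static const double invRTONF = 1.0 / RTONF;

static const double Ko = 5.4, Cao = 2.0, Nao = 140.0; // mM
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468; // um^3 scale
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;
static const double pKNa = 0.03;
static const double GCaL = 0.0000398;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncagam = 0.35;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double GpK = 0.0146, GpCa = 0.1238, KpCa = 0.0005;
static const double GbNa = 0.00029, GbCa = 0.000592;
static const double CAPACITANCE = 0.185; // uF/cm^2, concentration conversion
static const double inverseVcF2 = 1.0 / (2.0 * Vc * Frdy);
static const double inverseVcF  = 1.0 / (Vc * Frdy);
static const double inversevssF2 = 1.0 / (2.0 * Vss * Frdy);

// per-type maximal conductances (nS/pF)
static const double GNa_VM = 14.838, GNa_PF = 130.5744;
static const double Gto_ENDO = 0.073, Gto_EPI = 0.294, Gto_MID = 0.294, Gto_PF = 0.08184;
static const double GKr_VM = 0.153, GKr_PF = 0.0918;
static const double GKs_ENDOEPI = 0.392, GKs_MID = 0.098, GKs_PF = 0.2352;
static const double GK1_VM = 5.405, GK1_PF = 0.065;
static const double Gsus_PF = 0.0227;
static const double GfNa_PF = 0.0145654, GfK_PF = 0.0234346;

static double default_gk1(int ct) { return ct == CT_PURK ? GK1_PF : GK1_VM; }

struct TypeCond { double gna, gto, gkr, gks; };
static TypeCond type_cond(int ct) {
  switch (ct) {
  case CT_ENDO: return { GNa_VM, Gto_ENDO, GKr_VM, GKs_ENDOEPI };
  case CT_MID:  return { GNa_VM, Gto_MID,  GKr_VM, GKs_MID };
  case CT_EPI:  return { GNa_VM, Gto_EPI,  GKr_VM, GKs_ENDOEPI };
  case CT_PURK: return { GNa_PF, Gto_PF,   GKr_PF, GKs_PF };
  default: stop("unknown cell type code %d", ct);
  }
  return { 0, 0, 0, 0 }; // not reached
}

// ---------------------------------------------------------------------------
// voltage-dependent quantities (gate steady states, Rush-Larsen factors for a
// fixed dt, and current rectification/exponential factors)
struct VDep {
  double minf, mrl, hinf, hrl, jinf, jrl;
  double xr1inf, xr1rl, xr2inf, xr2rl, xsinf, xsrl;
  double dinf, drl, finf, frl, f2inf, f2rl;
  double rinf, rrl, sinf, srl;       // variant chosen by cell type
  double yinf, yrl, ainf, xk1inf;    // Purkinje only (else unused)
  double nacae1, nacae2n, nakrec, pkrec, cale2, calA;
  double k1rec;                      // function of V - EK (ventricular IK1)
};

// closed-form rate evaluation at voltage v; vek = v - EK for the ventricular
// inward rectifier. Fills the fields relevant to cell type ct.
static void vdep_direct(double v, double vek, int ct, double dt, VDep& g) {
  // fast sodium current gates (shared by both models)
  double mi = 1.0 / (1.0 + std::exp((-56.86 - v) / 9.03));
  g.minf = mi * mi;
  double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
              0.10 / (1.0 + std::exp((v - 50.0) / 200.0));
  g.mrl = std::exp(-dt / (am * bm));

  double hi = 1.0 / (1.0 + std::exp((v + 71.55) / 7.43));
  g.hinf = hi * hi;
  double ah, bh;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
  }
  g.hrl = std::exp(-dt * (ah + bh));

  g.jinf = g.hinf;
  double aj, bj;
  if (v >= -40.0) {
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    aj = (-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  g.jrl = std::exp(-dt * (aj + bj));

  // rapid delayed rectifier
  g.xr1inf = 1.0 / (1.0 + std::exp((-26.0 - v) / 7.0));
  double axr1 = 450.0 / (1.0 + std::exp((-45.0 - v) / 10.0));
  double bxr1 = 6.0 / (1.0 + std::exp((v + 30.0) / 11.5));
  g.xr1rl = std::exp(-dt / (axr1 * bxr1));
  g.xr2inf = 1.0 / (1.0 + std::exp((v + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + std::exp((-60.0 - v) / 20.0));
  double bxr2 = 1.12 / (1.0 + std::exp((v - 60.0) / 20.0));
  g.xr2rl = std::exp(-dt / (axr2 * bxr2));

  // slow delayed rectifier
  g.xsinf = 1.0 / (1.0 + std::exp((-5.0 - v) / 14.0));
  double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - v) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((v - 35.0) / 15.0));
  g.xsrl = std::exp(-dt / (axs * bxs + 80.0));

  // L-type calcium gates
  g.dinf = 1.0 / (1.0 + std::exp((-8.0 - v) / 7.5));
  double ad = 1.4 / (1.0 + std::exp((-35.0 - v) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((v + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + std::exp((50.0 - v) / 20.0));
  g.drl = std::exp(-dt / (ad * bd + gd));
  g.finf = 1.0 / (1.0 + std::exp((v + 20.0) / 7.0));
  double tf = 1102.5 * std::exp(-(v + 27.0) * (v + 27.0) / 225.0) +
              200.0 / (1.0 + std::exp((13.0 - v) / 10.0)) +
              180.0 / (1.0 + std::exp((v + 30.0) / 10.0)) + 20.0;
  g.frl = std::exp(-dt / tf);
  g.f2inf = 0.67 / (1.0 + std::exp((v + 35.0) / 7.0)) + 0.33;
  double tf2 = 562.0 * std::exp(-(v + 27.0) * (v + 27.0) / 240.0) +
               31.0 / (1.0 + std::exp((25.0 - v) / 10.0)) +
               80.0 / (1.0 + std::exp((v + 30.0) / 10.0));
  g.f2rl = std::exp(-dt / tf2);

  // transient outward gates differ between models and transmural variants
  if (ct == CT_PURK) {
    g.rinf = 1.0 / (1.0 + std::exp((20.0 - v) / 13.0));
    double tr = 10.45 * std::exp(-(v + 40.0) * (v + 40.0) / 1800.0) + 7.3;
    g.rrl = std::exp(-dt / tr);
    g.sinf = 1.0 / (1.0 + std::exp((v + 27.0) / 13.0));
    double ts = 85.0 * std::exp(-(v + 25.0) * (v + 25.0) / 320.0) +
                5.0 / (1.0 + std::exp((v - 40.0) / 5.0)) + 42.0;
    g.srl = std::exp(-dt / ts);
  } else {
    g.rinf = 1.0 / (1.0 + std::exp((20.0 - v) / 6.0));
    double tr = 9.5 * std::exp(-(v + 40.0) * (v + 40.0) / 1800.0) + 0.8;
    g.rrl = std::exp(-dt / tr);
    if (ct == CT_ENDO) {
      g.sinf = 1.0 / (1.0 + std::exp((v + 28.0) / 5.0));
      double ts = 1000.0 * std::exp(-(v + 67.0) * (v + 67.0) / 1000.0) + 8.0;
      g.srl = std::exp(-dt / ts);
    } else { // MID / EPI
      g.sinf = 1.0 / (1.0 + std::exp((v + 20.0) / 5.0));
      double ts = 85.0 * std::exp(-(v + 45.0) * (v + 45.0) / 320.0) +
                  5.0 / (1.0 + std::exp((v - 20.0) / 5.0)) + 3.0;
      g.srl = std::exp(-dt / ts);
    }
  }

  // Purkinje-only: funny current gate, sustained-current activation,
  // and the time-independent IK1 rectification
  if (ct == CT_PURK) {
    g.yinf = 1.0 / (1.0 + std::exp((v + 80.6) / 6.8));
    double ay = std::exp(-2.9 - 0.04 * v);
    double by = std::exp(3.6 + 0.11 * v);
    g.yrl = std::exp(-dt * (ay + by) / 4000.0);
    g.ainf = 1.0 / (1.0 + std::exp((5.0 - v) / 17.0));
    g.xk1inf = 1.0 / (1.0 + std::exp(0.1 * (v + 75.44)));
  } else {
    g.yinf = 0.0; g.yrl = 1.0; g.ainf = 0.0; g.xk1inf = 0.0;
  }

  // current factors
  g.nacae1 = std::exp(ncagam * v * invRTONF);
  g.nacae2n = std::exp((ncagam - 1.0) * v * invRTONF);
  g.nakrec = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v * invRTONF) +
                    0.0353 * std::exp(-v * invRTONF));
  g.pkrec = 1.0 / (1.0 + std::exp((25.0 - v) / 5.98));
  double x = 2.0 * (v - 15.0) * invRTONF;
  g.cale2 = std::exp(x);
  double xratio; // x / (exp(x) - 1), removable singularity at x = 0
  if (std::fabs(x) < 1e-4) xratio = 1.0 - x / 2.0 + x * x / 12.0;
  else xratio = x / (g.cale2 - 1.0);
  g.calA = 2.0 * Frdy * xratio; // 4 (V-15) F^2/(RT) / (e^x - 1) = 2 F * xratio

  // ventricular IK1 rectification as a function of V - EK
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (vek - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (vek + 100.0)) +
                std::exp(0.1 * (vek - 10.0))) /
               (1.0 + std::exp(-0.5 * vek));
  g.k1rec = ak1 / (ak1 + bk1);
}

// ---------------------------------------------------------------------------
// lookup table over voltage for all closed-form quantities above
// ventricular-model quantities occupy slots 0..30 so that a ventricular
// lookup touches only the first four cache lines of a row; the Purkinje-only
// slots sit at the end
static const int LUT_STRIDE = 40;
enum LutIdx {
  L_MINF = 0, L_MRL, L_HINF, L_HRL, L_JINF, L_JRL,
  L_XR1INF, L_XR1RL, L_XR2INF, L_XR2RL, L_XSINF, L_XSRL,
  L_DINF, L_DRL, L_FINF, L_FRL, L_F2INF, L_F2RL,
  L_RVINF, L_RVRL, L_SENINF, L_SENRL, L_SEPINF, L_SEPRL,
  L_K1REC, L_NACAE1, L_NACAE2N, L_NAKREC, L_PKREC, L_CALE2, L_CALA,
  L_RPINF, L_RPRL, L_SPINF, L_SPRL,
  L_YINF, L_YRL, L_AINF, L_XK1INF
};

struct Lut {
  double dt, vmin, dv, invdv;
  int n;
  std::vector<double> tab; // n * LUT_STRIDE, row-major per voltage sample
};

static std::unique_ptr<Lut> g_lut; // cached for the most recent dt

static void build_lut(double dt) {
  auto lut = std::make_unique<Lut>();
  lut->dt = dt;
  lut->vmin = -200.0;
  lut->dv = 0.05;
  lut->invdv = 1.0 / lut->dv;
  lut->n = (int)std::lround((200.0 - lut->vmin) / lut->dv) + 1;
  lut->tab.assign((size_t)lut->n * LUT_STRIDE, 0.0);
  VDep ge, gp, gm;
  for (int i = 0; i < lut->n; ++i) {
    double v = lut->vmin + i * lut->dv;
    // endo fills the shared gates + endo s; epi/M only differs in s; the
    // Purkinje variant adds r/s/y/a/xk1. k1rec is tabulated on the same axis
    // interpreted as V - EK.
    vdep_direct(v, v, CT_ENDO, dt, ge);
    vdep_direct(v, v, CT_EPI,  dt, gm);
    vdep_direct(v, v, CT_PURK, dt, gp);
    double* row = &lut->tab[(size_t)i * LUT_STRIDE];
    row[L_MINF] = ge.minf;     row[L_MRL] = ge.mrl;
    row[L_HINF] = ge.hinf;     row[L_HRL] = ge.hrl;
    row[L_JINF] = ge.jinf;     row[L_JRL] = ge.jrl;
    row[L_XR1INF] = ge.xr1inf; row[L_XR1RL] = ge.xr1rl;
    row[L_XR2INF] = ge.xr2inf; row[L_XR2RL] = ge.xr2rl;
    row[L_XSINF] = ge.xsinf;   row[L_XSRL] = ge.xsrl;
    row[L_DINF] = ge.dinf;     row[L_DRL] = ge.drl;
    row[L_FINF] = ge.finf;     row[L_FRL] = ge.frl;
    row[L_F2INF] = ge.f2inf;   row[L_F2RL] = ge.f2rl;
    row[L_RVINF] = ge.rinf;    row[L_RVRL] = ge.rrl;
    row[L_SENINF] = ge.sinf;   row[L_SENRL] = ge.srl;
    row[L_SEPINF] = gm.sinf;   row[L_SEPRL] = gm.srl;
    row[L_RPINF] = gp.rinf;    row[L_RPRL] = gp.rrl;
    row[L_SPINF] = gp.sinf;    row[L_SPRL] = gp.srl;
    row[L_YINF] = gp.yinf;     row[L_YRL] = gp.yrl;
    row[L_AINF] = gp.ainf;     row[L_XK1INF] = gp.xk1inf;
    row[L_K1REC] = ge.k1rec;
    row[L_NACAE1] = ge.nacae1; row[L_NACAE2N] = ge.nacae2n;
    row[L_NAKREC] = ge.nakrec; row[L_PKREC] = ge.pkrec;
    row[L_CALE2] = ge.cale2;   row[L_CALA] = ge.calA;
  }
  g_lut = std::move(lut);
}

static inline const Lut& lut_for(double dt) {
  if (!g_lut || g_lut->dt != dt) build_lut(dt);
  return *g_lut;
}

struct LutAt {
  const double *r0, *r1;
  double w;
};

static inline LutAt lut_locate(const Lut& lut, double v) {
  double u = (v - lut.vmin) * lut.invdv;
  int i = (int)u;
  if (i < 0) { i = 0; u = 0.0; }
  if (i >= lut.n - 1) { i = lut.n - 2; u = (double)(lut.n - 1); }
  LutAt at;
  at.r0 = &lut.tab[(size_t)i * LUT_STRIDE];
  at.r1 = at.r0 + LUT_STRIDE;
  at.w = u - i;
  return at;
}

static inline double lut_get(const LutAt& at, int q) {
  return at.r0[q] + (at.r1[q] - at.r0[q]) * at.w;
}

static void vdep_lut(double v, double vek, int ct, const Lut& lut, VDep& g) {
  LutAt at = lut_locate(lut, v);
  g.minf = lut_get(at, L_MINF);     g.mrl = lut_get(at, L_MRL);
  g.hinf = lut_get(at, L_HINF);     g.hrl = lut_get(at, L_HRL);
  g.jinf = lut_get(at, L_JINF);     g.jrl = lut_get(at, L_JRL);
  g.xr1inf = lut_get(at, L_XR1INF); g.xr1rl = lut_get(at, L_XR1RL);
  g.xr2inf = lut_get(at, L_XR2INF); g.xr2rl = lut_get(at, L_XR2RL);
  g.xsinf = lut_get(at, L_XSINF);   g.xsrl = lut_get(at, L_XSRL);
  g.dinf = lut_get(at, L_DINF);     g.drl = lut_get(at, L_DRL);
  g.finf = lut_get(at, L_FINF);     g.frl = lut_get(at, L_FRL);
  g.f2inf = lut_get(at, L_F2INF);   g.f2rl = lut_get(at, L_F2RL);
  if (ct == CT_PURK) {
    g.rinf = lut_get(at, L_RPINF);  g.rrl = lut_get(at, L_RPRL);
    g.sinf = lut_get(at, L_SPINF);  g.srl = lut_get(at, L_SPRL);
    g.yinf = lut_get(at, L_YINF);   g.yrl = lut_get(at, L_YRL);
    g.ainf = lut_get(at, L_AINF);   g.xk1inf = lut_get(at, L_XK1INF);
    g.k1rec = 0.0;
  } else {
    g.rinf = lut_get(at, L_RVINF);  g.rrl = lut_get(at, L_RVRL);
    if (ct == CT_ENDO) { g.sinf = lut_get(at, L_SENINF); g.srl = lut_get(at, L_SENRL); }
    else               { g.sinf = lut_get(at, L_SEPINF); g.srl = lut_get(at, L_SEPRL); }
    g.yinf = 0.0; g.yrl = 1.0; g.ainf = 0.0; g.xk1inf = 0.0;
    LutAt atk = lut_locate(lut, vek);
    g.k1rec = lut_get(atk, L_K1REC);
  }
  g.nacae1 = lut_get(at, L_NACAE1);
  g.nacae2n = lut_get(at, L_NACAE2N);
  g.nakrec = lut_get(at, L_NAKREC);
  g.pkrec = lut_get(at, L_PKREC);
  g.cale2 = lut_get(at, L_CALE2);
  g.calA = lut_get(at, L_CALA);
}

// ---------------------------------------------------------------------------
// membrane currents (pA/pF)
struct Currents {
  double ina, ik1, ito, ikr, iks, ical, inaca, inak, ipk, ipca, ibca, ibna;
  double ifna, ifk, isus; // Purkinje only, zero otherwise
  double iion;
};

struct Rev { double ek, ena, eks, eca; };

static inline Rev reversal_potentials(const double* s) {
  Rev r;
  r.ek = RTONF * std::log(Ko / s[SKI]);
  r.ena = RTONF * std::log(Nao / s[SNAI]);
  r.eks = RTONF * std::log((Ko + pKNa * Nao) / (s[SKI] + pKNa * s[SNAI]));
  r.eca = 0.5 * RTONF * std::log(Cao / s[SCAI]);
  return r;
}

static void eval_currents(const double* s, int ct, double gk1, double v,
                          const Rev& rev, const VDep& g, Currents& c) {
  TypeCond tc = type_cond(ct);
  double Nai = s[SNAI], Cai = s[SCAI], CaSS = s[SCASS];
  double Ek = rev.ek, Ena = rev.ena, Eks = rev.eks, Eca = rev.eca;

  c.ina = tc.gna * s[SM] * s[SM] * s[SM] * s[SH] * s[SJ] * (v - Ena);
  c.ical = GCaL * s[SD] * s[SF] * s[SF2] * s[SFCASS] * g.calA *
           (0.25 * CaSS * g.cale2 - Cao);
  c.ito = tc.gto * s[SR] * s[SS] * (v - Ek);
  c.ikr = tc.gkr * std::sqrt(Ko / 5.4) * s[SXR1] * s[SXR2] * (v - Ek);
  c.iks = tc.gks * s[SXS] * s[SXS] * (v - Eks);
  if (ct == CT_PURK) {
    // time-independent rectification; note the +8 mV shift of the reversal
    c.ik1 = gk1 * g.xk1inf * (v - 8.0 - Ek);
    c.ifna = GfNa_PF * s[SY] * (v - Ena);
    c.ifk = GfK_PF * s[SY] * (v - Ek);
    c.isus = Gsus_PF * g.ainf * (v - Ek);
  } else {
    c.ik1 = gk1 * g.k1rec * (v - Ek);
    c.ifna = 0.0; c.ifk = 0.0; c.isus = 0.0;
  }
  c.inaca = knaca *
    (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
    (1.0 / (KmCa + Cao)) *
    (1.0 / (1.0 + ksat * g.nacae2n)) *
    (g.nacae1 * Nai * Nai * Nai * Cao -
     g.nacae2n * Nao * Nao * Nao * Cai * 2.5);
  c.inak = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) * g.nakrec;
  c.ipca = GpCa * Cai / (KpCa + Cai);
  c.ipk = GpK * g.pkrec * (v - Ek);
  c.ibna = GbNa * (v - Ena);
  c.ibca = GbCa * (v - Eca);
  c.iion = c.ina + c.ik1 + c.ito + c.ikr + c.iks + c.ical + c.inaca + c.inak +
           c.ipk + c.ipca + c.ibca + c.ibna + c.ifna + c.ifk + c.isus;
}

// ---------------------------------------------------------------------------
// one ionic step: currents at the (possibly diffusion-incremented) voltage,
// forward-Euler voltage and concentration updates, Rush-Larsen gate updates
static inline void step_ionic(double* s, int ct, double gk1, double dt,
                              double istim, double v, const Rev& rev,
                              const VDep& g) {
  Currents c;
  eval_currents(s, ct, gk1, v, rev, g, c);
  double itot = c.iion + istim;

  // calcium subsystem (analytic buffering as in the published code)
  double CaSR = s[SCASR], CaSS = s[SCASS], Cai = s[SCAI];
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
  double k1 = k1p / kCaSR;
  double k2 = k2p * kCaSR;
  double dRR = k4 * (1.0 - s[SRR]) - k2 * CaSS * s[SRR];
  s[SRR] += dt * dRR;
  double sOO = k1 * CaSS * CaSS * s[SRR] / (k3 + k1 * CaSS * CaSS);

  double Irel = Vrel * sOO * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + Kup * Kup / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
  double dCaSR = dt * (Iup - Irel - Ileak);
  double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
  double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
  s[SCASR] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
  double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                       (-c.ical * inversevssF2 * CAPACITANCE));
  double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
  double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
  s[SCASS] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  double CaBuf = Bufc * Cai / (Cai + Kbufc);
  double dCai = dt * ((-(c.ibca + c.ipca - 2.0 * c.inaca) * inverseVcF2 * CAPACITANCE) -
                      (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
  double cc = Kbufc * (CaBuf + dCai + Cai);
  s[SCAI] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  double dNai = -(c.ina + c.ibna + c.ifna + 3.0 * c.inak + 3.0 * c.inaca) *
                inverseVcF * CAPACITANCE;
  s[SNAI] += dt * dNai;
  double dKi = -(istim + c.ik1 + c.ito + c.isus + c.ifk + c.ikr + c.iks -
                 2.0 * c.inak + c.ipk) * inverseVcF * CAPACITANCE;
  s[SKI] += dt * dKi;

  // Rush-Larsen gate updates
  s[SM]   = g.minf   + (s[SM]   - g.minf)   * g.mrl;
  s[SH]   = g.hinf   + (s[SH]   - g.hinf)   * g.hrl;
  s[SJ]   = g.jinf   + (s[SJ]   - g.jinf)   * g.jrl;
  s[SXR1] = g.xr1inf + (s[SXR1] - g.xr1inf) * g.xr1rl;
  s[SXR2] = g.xr2inf + (s[SXR2] - g.xr2inf) * g.xr2rl;
  s[SXS]  = g.xsinf  + (s[SXS]  - g.xsinf)  * g.xsrl;
  s[SR]   = g.rinf   + (s[SR]   - g.rinf)   * g.rrl;
  s[SS]   = g.sinf   + (s[SS]   - g.sinf)   * g.srl;
  s[SD]   = g.dinf   + (s[SD]   - g.dinf)   * g.drl;
  s[SF]   = g.finf   + (s[SF]   - g.finf)   * g.frl;
  s[SF2]  = g.f2inf  + (s[SF2]  - g.f2inf)  * g.f2rl;
  // calcium-dependent inactivation gate (depends on CaSS, not V)
  double fcinf = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  double tfc = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;
  s[SFCASS] = fcinf + (s[SFCASS] - fcinf) * std::exp(-dt / tfc);
  if (ct == CT_PURK) s[SY] = g.yinf + (s[SY] - g.yinf) * g.yrl;

  s[SV] = v - dt * itot;
}

static inline void check_voltage(double v, double t, int cell) {
  if (!(v > -250.0 && v < 250.0)) {
    if (cell >= 0)
      stop("numerical instability: membrane potential %.3f mV at t = %.3f ms (cell index %d); reduce dt", v, t, cell + 1);
    stop("numerical instability: membrane potential %.3f mV at t = %.3f ms; reduce dt", v, t);
  }
}

// one full cell step (diffusion increment dvdiff folded into the voltage)
static inline void step_one(double* s, int ct, double gk1, double dt,
                            double istim, double dvdiff, bool exact,
                            const Lut* lut, double t, int cell) {
  double v = s[SV] + dvdiff;
  check_voltage(v, t, cell);
  Rev rev = reversal_potentials(s);
  VDep g;
  if (exact) vdep_direct(v, v - rev.ek, ct, dt, g);
  else vdep_lut(v, v - rev.ek, ct, *lut, g);
  step_ionic(s, ct, gk1, dt, istim, v, rev, g);
}

// ---------------------------------------------------------------------------
// published initial conditions
// [[Rcpp::export]]
NumericVector cpp_init_state(int cell_type) {
  NumericVector s(NSTATE);
  if (cell_type == CT_PURK) {
    s[SV] = -69.1370441635924;
    s[SKI] = 136.781894160227;
    s[SNAI] = 8.80420286531673;
    s[SCAI] = 0.000101878186157052;
    s[SCASS] = 0.000446818714055411;
    s[SCASR] = 3.10836886659417;
    s[SRR] = 0.9068;
    s[SM] = 0.0417391656294997;
    s[SH] = 0.190678733735145;
    s[SJ] = 0.238219836154029;
    s[SXR1] = 0.00550281999719088;
    s[SXR2] = 0.313213286437995;
    s[SXS] = 0.00953708522974789;
    s[SR] = 0.00103618091196912;
    s[SS] = 0.96386101799501;
    s[SD] = 0.000287906256206415;
    s[SF] = 0.989328560287987;
    s[SF2] = 0.995474890442185;
    s[SFCASS] = 0.999955429598213;
    s[SY] = 0.0457562667986602;
  } else if (cell_type == CT_ENDO || cell_type == CT_MID || cell_type == CT_EPI) {
    s[SV] = -86.2;
    s[SKI] = 138.3;
    s[SNAI] = 7.67;
    s[SCAI] = 0.00007;
    s[SCASS] = 0.00007;
    s[SCASR] = 1.3;
    s[SRR] = 1.0;
    s[SM] = 0.0;
    s[SH] = 0.75;
    s[SJ] = 0.75;
    s[SXR1] = 0.0;
    s[SXR2] = 1.0;
    s[SXS] = 0.0;
    s[SR] = 0.0;
    s[SS] = 1.0;
    s[SD] = 0.0;
    s[SF] = 1.0;
    s[SF2] = 1.0;
    s[SFCASS] = 1.0;
    s[SY] = 0.0;
  } else {
    stop("unknown cell type code %d", cell_type);
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_compute_currents(NumericVector state, int cell_type, double gk1) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state variable at position %d", i + 1);
  double v = state[SV];
  Rev rev = reversal_potentials(REAL(state));
  VDep g;
  vdep_direct(v, v - rev.ek, cell_type, 0.02, g);
  Currents c;
  eval_currents(REAL(state), cell_type, gk1, v, rev, g, c);
  return NumericVector::create(
    _["i_na"] = c.ina, _["i_k1"] = c.ik1, _["i_to"] = c.ito,
    _["i_kr"] = c.ikr, _["i_ks"] = c.iks, _["i_cal"] = c.ical,
    _["i_naca"] = c.inaca, _["i_nak"] = c.inak, _["i_pk"] = c.ipk,
    _["i_pca"] = c.ipca, _["i_bca"] = c.ibca, _["i_bna"] = c.ibna,
    _["i_f_na"] = c.ifna, _["i_f_k"] = c.ifk, _["i_sus"] = c.isus,
    _["i_ion"] = c.iion);
}

// [[Rcpp::export]]
NumericVector cpp_step_cell(NumericVector state, int cell_type, double gk1,
                            double dt, int n_steps, double i_stim, bool exact) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (!(dt > 0)) stop("dt must be positive");
  type_cond(cell_type); // validates the code
  NumericVector out = clone(state);
  double* s = REAL(out);
  const Lut* lut = exact ? nullptr : &lut_for(dt);
  for (int k = 0; k < n_steps; ++k)
    step_one(s, cell_type, gk1, dt, i_stim, 0.0, exact, lut, k * dt, -1);
  check_voltage(s[SV], n_steps * dt, -1);
  return out;
}

// Single-cell run with optional square stimulus pulse; records vm every
// sample_every steps (plus the initial sample).
// [[Rcpp::export]]
List cpp_run_cell(NumericVector state0, int cell_type, double gk1, double dt,
                  double duration_ms, double sample_dt,
                  double istim_amp, double istim_start, double istim_dur,
                  bool exact) {
  if (state0.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (!(dt > 0) || !(duration_ms > 0)) stop("dt and duration must be positive");
  type_cond(cell_type);
  long long nsteps = (long long)std::llround(duration_ms / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  long long nsamp = nsteps / sample_every + 1;
  NumericVector times((R_xlen_t)nsamp), vm((R_xlen_t)nsamp);
  NumericVector st = clone(state0);
  double* s = REAL(st);
  const Lut* lut = exact ? nullptr : &lut_for(dt);
  times[0] = 0.0; vm[0] = s[SV];
  R_xlen_t isamp = 1;
  for (long long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double istim = (istim_amp != 0.0 && t >= istim_start &&
                    t < istim_start + istim_dur) ? istim_amp : 0.0;
    step_one(s, cell_type, gk1, dt, istim, 0.0, exact, lut, t, -1);
    if ((k + 1) % sample_every == 0) {
      times[isamp] = (k + 1) * dt;
      vm[isamp] = s[SV];
      ++isamp;
    }
    if ((k & 0xFFFFF) == 0xFFFFF) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = times, _["vm"] = vm, _["final_state"] = st);
}

// ---------------------------------------------------------------------------
// 2D monodomain tissue stepping over a compacted cell list.
//
// state0: NSTATE x ncell matrix; nbr: ncell x 4 matrix of 0-based coupled
// neighbour indices (-1 = no coupled neighbour; zero-flux). dcoef = D/dh^2 in
// 1/ms. Operator splitting: the diffusion increment for the step is computed
// from the voltages at the start of the step and folded into the ionic update.
// [[Rcpp::export]]
List cpp_run_tissue(NumericMatrix state0, IntegerVector ctype, NumericVector gk1,
                    IntegerMatrix nbr, double dcoef, double dt, double t0,
                    double duration_ms, IntegerVector probes, double sample_dt,
                    double snapshot_dt) {
  int ncell = state0.ncol();
  if (state0.nrow() != NSTATE) stop("state matrix must have %d rows", NSTATE);
  if (ctype.size() != ncell || gk1.size() != ncell || nbr.nrow() != ncell)
    stop("ctype/gk1/nbr dimensions do not match the number of cells");
  if (nbr.ncol() != 4) stop("nbr must have 4 columns");
  if (!(dcoef * dt < 0.25))
    stop("stability violated: D*dt/dh^2 = %.4f must be < 0.25", dcoef * dt);
  for (int i = 0; i < ncell; ++i) type_cond(ctype[i]);

  long long nsteps = (long long)std::llround(duration_ms / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  long long nsamp = nsteps / sample_every + 1;
  int nprobe = probes.size();
  NumericVector times((R_xlen_t)nsamp);
  NumericMatrix traces((R_xlen_t)nsamp, nprobe);

  long long snap_every = 0, nsnap = 0;
  if (snapshot_dt > 0) {
    snap_every = std::max((long long)1, (long long)std::llround(snapshot_dt / dt));
    nsnap = nsteps / snap_every + 1;
  }
  NumericMatrix snaps(nsnap > 0 ? ncell : 0, (R_xlen_t)nsnap);
  NumericVector snap_times((R_xlen_t)nsnap);

  // cell-major working copy for cache locality
  std::vector<double> st((size_t)ncell * NSTATE);
  for (int i = 0; i < ncell; ++i)
    for (int q = 0; q < NSTATE; ++q)
      st[(size_t)i * NSTATE + q] = state0(q, i);

  std::vector<double> dvdiff(ncell);
  const Lut& lut = lut_for(dt);
  const int* nb = INTEGER(nbr); // column-major: nb[c*ncell + i]
  const int* ctp = INTEGER(ctype);
  const double* gk = REAL(gk1);

  R_xlen_t isamp = 0, isnap = 0;
  times[isamp] = t0;
  for (int p = 0; p < nprobe; ++p)
    traces(isamp, p) = st[(size_t)probes[p] * NSTATE + SV];
  ++isamp;
  if (nsnap > 0) {
    snap_times[isnap] = t0;
    for (int i = 0; i < ncell; ++i) snaps(i, isnap) = st[(size_t)i * NSTATE + SV];
    ++isnap;
  }

  double ddt = dcoef * dt;
  for (long long k = 0; k < nsteps; ++k) {
    double t = t0 + k * dt;
    // diffusion increments from start-of-step voltages
    for (int i = 0; i < ncell; ++i) {
      double vi = st[(size_t)i * NSTATE + SV];
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        int j = nb[(size_t)c * ncell + i];
        if (j >= 0) acc += st[(size_t)j * NSTATE + SV] - vi;
      }
      dvdiff[i] = ddt * acc;
    }
    for (int i = 0; i < ncell; ++i)
      step_one(&st[(size_t)i * NSTATE], ctp[i], gk[i], dt, 0.0, dvdiff[i],
               false, &lut, t, i);
    if ((k + 1) % sample_every == 0) {
      times[isamp] = t0 + (k + 1) * dt;
      for (int p = 0; p < nprobe; ++p)
        traces(isamp, p) = st[(size_t)probes[p] * NSTATE + SV];
      ++isamp;
    }
    if (nsnap > 0 && (k + 1) % snap_every == 0) {
      snap_times[isnap] = t0 + (k + 1) * dt;
      for (int i = 0; i < ncell; ++i) snaps(i, isnap) = st[(size_t)i * NSTATE + SV];
      ++isnap;
    }
    if ((k & 0x3FFF) == 0x3FFF) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_state(NSTATE, ncell);
  for (int i = 0; i < ncell; ++i)
    for (int q = 0; q < NSTATE; ++q)
      final_state(q, i) = st[(size_t)i * NSTATE + q];

  return List::create(
    _["times"] = times, _["traces"] = traces,
    _["snap_times"] = snap_times, _["snapshots"] = snaps,
    _["final_state"] = final_state, _["t_end"] = t0 + nsteps * dt);
}
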