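// O'Hara-Rudy human ventricular myocyte (2011 lineage), endo/M/epi variants.
// Transcribed from the published ORd model code.  Currents in uA/uF,
// concentrations mM, time ms.  CaMK-active fraction can be scaled
// (heart-failure "CaMKa 150%"), and the non-phosphorylated RyR release
// half-saturation (jrel_ec50, 1.5 mM cajsr) is a parameter.
//
// The fixed-step path uses voltage-grid lookup tables (two tables: epi and
// non-epi kinetics, which differ in the I_to inactivation time constants);
// gate TAU slots hold exp(-dt/tau).  Tables contain kinetic constants only;
// all remodelable magnitudes enter outside.  The derivative path evaluates
// the closed forms directly.

#include "models.h"
#include <cmath>
#include <vector>

namespace hfs {

// state indices (0 = Vm)
enum {
  oV = 0, onai, onass, oki, okss, ocai, ocass, ocansr, ocajsr, om, ohf, ohs,
  oj, ohsp, ojp, omL, ohL, ohLp, oa, oiF, oiS, oap, oiFp, oiSp, od, off_,
  ofs, ofcaf, ofcas, ojca, onca, offp, ofcafp, oxrf, oxrs, oxs1, oxs2, oxk1,
  oJrelnp, oJrelp, oCaMKt
};

// parameter indices
enum {
  qGNa = 0, qGNaL, qThL, qGto, qPCa, qGKr, qGKs, qGK1, qGncx, qPnak, qGKb,
  qPNab, qPCab, qGpCa, qJupBase, qLeakBase, qCamkScale, qJrelEc50,
  qJrelScale, qCmdnMax, qIsEpi
};

static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double R = 8314.0, T = 310.0, F = 96485.0;
static const double FRT = F / (R * T);
static const double L = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * L;
static const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

static const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
static const double CaMKo = 0.05, KmCaM = 0.0015;
static const double PKNa = 0.01833;
// NCX kinetic constants
static const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
static const double wna = 6e4, wca = 6e4, wnaca = 5e3;
static const double kcaon = 1.5e6, kcaoff = 5e3;
static const double qna = 0.5224, qca = 0.1670;
static const double KmCaAct = 150e-6;
// INaK kinetic constants
static const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
static const double k3p_n = 1899.0, k3m = 79300.0, k4p_n = 639.0, k4m = 40.0;
static const double Knai0 = 9.073, Knao0 = 27.78, delta_nak = -0.1550;
static const double Kki = 0.5, Kko = 0.3582;
static const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
static const double H_ = 1e-7, eP = 4.2, Khp = 1.698e-7, Knap = 224.0,
                    Kxkur = 292.0;

static inline double cube(double x) { return x * x * x; }
static inline double sqr(double x) { return x * x; }

void ord_default_params(int cell_class, double* p) {
  const bool epi = (cell_class == EPI), mid = (cell_class == MID);
  p[qGNa] = 75.0;
  p[qGNaL] = 0.0075 * (epi ? 0.6 : 1.0);
  p[qThL] = 200.0;
  p[qGto] = 0.02 * ((epi || mid) ? 4.0 : 1.0);
  p[qPCa] = 0.0001 * (epi ? 1.2 : (mid ? 2.5 : 1.0));
  p[qGKr] = 0.046 * (epi ? 1.3 : (mid ? 0.8 : 1.0));
  p[qGKs] = 0.0034 * (epi ? 1.4 : 1.0);
  p[qGK1] = 0.1908 * (epi ? 1.2 : (mid ? 1.3 : 1.0));
  p[qGncx] = 0.0008 * (epi ? 1.1 : (mid ? 1.4 : 1.0));
  p[qPnak] = 30.0 * (epi ? 0.9 : (mid ? 0.7 : 1.0));
  p[qGKb] = 0.003 * (epi ? 0.6 : 1.0);
  p[qPNab] = 3.75e-10;
  p[qPCab] = 2.5e-8;
  p[qGpCa] = 0.0005;
  p[qJupBase] = 0.004375 * (epi ? 1.3 : 1.0);
  p[qLeakBase] = 0.0039375;
  p[qCamkScale] = 1.0;
  p[qJrelEc50] = 1.5;
  p[qJrelScale] = (mid ? 1.7 : 1.0);
  p[qCmdnMax] = 0.05 * (epi ? 1.3 : 1.0);
  p[qIsEpi] = epi ? 1.0 : 0.0;
}

void ord_init(double* y) {
  // published initial conditions of the base model
  y[oV] = -87.0;
  y[onai] = 7.0;
  y[onass] = 7.0;
  y[oki] = 145.0;
  y[okss] = 145.0;
  y[ocai] = 1e-4;
  y[ocass] = 1e-4;
  y[ocansr] = 1.2;
  y[ocajsr] = 1.2;
  y[om] = 0.0;
  y[ohf] = 1.0;
  y[ohs] = 1.0;
  y[oj] = 1.0;
  y[ohsp] = 1.0;
  y[ojp] = 1.0;
  y[omL] = 0.0;
  y[ohL] = 1.0;
  y[ohLp] = 1.0;
  y[oa] = 0.0;
  y[oiF] = 1.0;
  y[oiS] = 1.0;
  y[oap] = 0.0;
  y[oiFp] = 1.0;
  y[oiSp] = 1.0;
  y[od] = 0.0;
  y[off_] = 1.0;
  y[ofs] = 1.0;
  y[ofcaf] = 1.0;
  y[ofcas] = 1.0;
  y[ojca] = 1.0;
  y[onca] = 0.0;
  y[offp] = 1.0;
  y[ofcafp] = 1.0;
  y[oxrf] = 0.0;
  y[oxrs] = 0.0;
  y[oxs1] = 0.0;
  y[oxs2] = 0.0;
  y[oxk1] = 1.0;
  y[oJrelnp] = 0.0;
  y[oJrelp] = 0.0;
  y[oCaMKt] = 0.0;
}

// ---------------------------------------------------------------------------
// voltage-dependent kinetics: gate pairs (INF, TAU) then scalars
enum {
  OV_M = 0, OV_HF = 2, OV_HS = 4, OV_J = 6, OV_HSP = 8, OV_JP = 10,
  OV_ML = 12, OV_A = 14, OV_IF = 16, OV_IS = 18, OV_AP = 20, OV_IFP = 22,
  OV_ISP = 24, OV_D = 26, OV_FF = 28, OV_FS = 30, OV_FCAF = 32, OV_FCAS = 34,
  OV_JCA = 36, OV_FFP = 38, OV_FCAFP = 40, OV_XRF = 42, OV_XRS = 44,
  OV_XS1 = 46, OV_XS2 = 48, OV_XK1 = 50,
  OV_HLINF = 52, OV_HLPINF, OV_HCA, OV_HNA, OV_KNAI, OV_KNAO, OV_E1V,
  OV_E2V, OV_XKB, OV_RKR, OV_RK1, ORD_NVD
};
#define INF(s) (s)
#define TAU(s) ((s) + 1)

static void ord_vdep(double v, bool epi, double* o) {
  const double vfrt = v * FRT;
  o[INF(OV_M)] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  const double tm = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                           8.552 * std::exp(-(v + 77.42) / 5.955));
  o[TAU(OV_M)] = tm;
  const double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  o[INF(OV_HF)] = hss;
  o[TAU(OV_HF)] = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                         6.149 * std::exp((v + 0.5096) / 20.27));
  const double ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                            0.3343 * std::exp((v + 5.730) / 56.66));
  o[INF(OV_HS)] = hss;
  o[TAU(OV_HS)] = ths;
  const double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                                   0.3052 * std::exp((v + 0.9941) / 38.45));
  o[INF(OV_J)] = hss;
  o[TAU(OV_J)] = tj;
  o[INF(OV_HSP)] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  o[TAU(OV_HSP)] = 3.0 * ths;
  o[INF(OV_JP)] = hss;
  o[TAU(OV_JP)] = 1.46 * tj;
  o[INF(OV_ML)] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  o[TAU(OV_ML)] = tm;
  const double ass = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  const double ta = 1.0515 /
      (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
       3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  o[INF(OV_A)] = ass;
  o[TAU(OV_A)] = ta;
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  const double delta_epi =
      epi ? (1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0))) : 1.0;
  double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                              0.08004 * std::exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * std::exp((v + 114.1) / 8.079));
  tiF *= delta_epi;
  tiS *= delta_epi;
  o[INF(OV_IF)] = iss;
  o[TAU(OV_IF)] = tiF;
  o[INF(OV_IS)] = iss;
  o[TAU(OV_IS)] = tiS;
  o[INF(OV_AP)] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  o[TAU(OV_AP)] = ta;
  const double dti_develop = 1.354 + 1e-4 / (std::exp((v - 167.4) / 15.89) +
                                             std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  o[INF(OV_IFP)] = iss;
  o[TAU(OV_IFP)] = dti_develop * dti_recover * tiF;
  o[INF(OV_ISP)] = iss;
  o[TAU(OV_ISP)] = dti_develop * dti_recover * tiS;
  o[INF(OV_D)] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  o[TAU(OV_D)] = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                              std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  const double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                                  0.0045 * std::exp((v + 20.0) / 10.0));
  const double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                                     0.000035 * std::exp((v + 5.0) / 6.0));
  o[INF(OV_FF)] = fss;
  o[TAU(OV_FF)] = tff;
  o[INF(OV_FS)] = fss;
  o[TAU(OV_FS)] = tfs;
  const double fcass = fss;
  const double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                                    0.04 * std::exp((v - 4.0) / 7.0));
  const double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                      0.00012 * std::exp(v / 7.0));
  o[INF(OV_FCAF)] = fcass;
  o[TAU(OV_FCAF)] = tfcaf;
  o[INF(OV_FCAS)] = fcass;
  o[TAU(OV_FCAS)] = tfcas;
  o[INF(OV_JCA)] = fcass;
  o[TAU(OV_JCA)] = 75.0;
  o[INF(OV_FFP)] = fss;
  o[TAU(OV_FFP)] = 2.5 * tff;
  o[INF(OV_FCAFP)] = fcass;
  o[TAU(OV_FCAFP)] = 2.5 * tfcaf;
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  o[INF(OV_XRF)] = xrss;
  o[TAU(OV_XRF)] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                                  4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  o[INF(OV_XRS)] = xrss;
  o[TAU(OV_XRS)] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                                  1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  o[INF(OV_XS1)] = xs1ss;
  o[TAU(OV_XS1)] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                                  0.001292 * std::exp(-(v + 210.0) / 230.0));
  o[INF(OV_XS2)] = xs1ss;
  o[TAU(OV_XS2)] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                          0.0193 * std::exp(-(v + 66.54) / 31.0));
  o[INF(OV_XK1)] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                         (1.5692 * ko + 3.8115)));
  o[TAU(OV_XK1)] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                            std::exp((v + 236.8) / 69.33));
  o[OV_HLINF] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  o[OV_HLPINF] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  o[OV_HCA] = std::exp(qca * vfrt);
  o[OV_HNA] = std::exp(qna * vfrt);
  o[OV_KNAI] = Knai0 * std::exp(delta_nak * vfrt / 3.0);
  o[OV_KNAO] = Knao0 * std::exp((1.0 - delta_nak) * vfrt / 3.0);
  o[OV_E1V] = std::exp(vfrt);
  o[OV_E2V] = std::exp(2.0 * vfrt);
  o[OV_XKB] = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  o[OV_RKR] = 1.0 / ((1.0 + std::exp((v + 55.0) / 75.0)) *
                     (1.0 + std::exp((v - 10.0) / 30.0)));
  o[OV_RK1] = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
}

struct OrdVTab {
  double dt = -1.0;
  double vmin, inv_dv;
  int n;
  std::vector<double> d;
};
static OrdVTab& ord_vtab(double dt, bool epi) {
  static OrdVTab T[2];
  OrdVTab& t = T[epi ? 1 : 0];
  if (t.dt != dt) {
    t.dt = dt;
    t.vmin = -150.0;
    const double vmax = 100.0;
    t.n = 10001;
    t.inv_dv = (t.n - 1) / (vmax - t.vmin);
    t.d.resize((size_t)t.n * ORD_NVD);
    for (int i = 0; i < t.n; ++i) {
      double* row = &t.d[(size_t)i * ORD_NVD];
      ord_vdep(t.vmin + i / t.inv_dv, epi, row);
      for (int g = OV_M; g <= OV_XK1; g += 2) row[TAU(g)] = std::exp(-dt / row[TAU(g)]);
    }
  }
  return t;
}

// log-concentration table for the IKs Ca-sensitivity factor
struct KsTab {
  double lmin, inv_dl;
  int n;
  std::vector<double> d;
};
static KsTab& ks_tab() {
  static KsTab T;
  if (T.d.empty()) {
    T.lmin = std::log(1e-9);
    const double lmax = std::log(10.0);
    T.n = 4000;
    T.inv_dl = (T.n - 1) / (lmax - T.lmin);
    T.d.resize(T.n);
    for (int i = 0; i < T.n; ++i) {
      const double x = std::exp(T.lmin + i / T.inv_dl);
      T.d[i] = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / x, 1.4));
    }
  }
  return T;
}
static inline double ksca_look(double cai) {
  const KsTab& T = ks_tab();
  double u = (fast_log(cai) - T.lmin) * T.inv_dl;
  if (u < 0) u = 0;
  if (u > T.n - 1.001) u = T.n - 1.001;
  const int i = (int)u;
  const double w = u - i;
  return T.d[i] + w * (T.d[i + 1] - T.d[i]);
}

// exp(-x) for small non-negative x; falls back to exp beyond
static inline double em(double x) {
  return (x < 0.1) ? 1.0 - x * (1.0 - 0.5 * x * (1.0 - x / 3.0)) : std::exp(-x);
}

static double ord_core(double* y, const double* p, double Istim, double dt,
                       double* dy, bool do_step) {
  const double v = y[oV];
  double vdbuf[ORD_NVD];
  const double* vd;
  if (do_step) {
    const OrdVTab& t = ord_vtab(dt, p[qIsEpi] > 0.5);
    double u = (v - t.vmin) * t.inv_dv;
    if (u < 0) u = 0;
    if (u > t.n - 1.001) u = t.n - 1.001;
    const int ii = (int)u;
    const double w = u - ii;
    const double* a = &t.d[(size_t)ii * ORD_NVD];
    const double* b = a + ORD_NVD;
    for (int s = 0; s < ORD_NVD; ++s) vdbuf[s] = a[s] + w * (b[s] - a[s]);
    vd = vdbuf;
  } else {
    ord_vdep(v, p[qIsEpi] > 0.5, vdbuf);
    vd = vdbuf;
  }

  const double nai = y[onai], nass = y[onass], ki = y[oki], kss = y[okss];
  const double cai = y[ocai], cass = y[ocass];
  const double cansr = y[ocansr], cajsr = y[ocajsr];
  const double m = y[om], hf = y[ohf], hs = y[ohs], j = y[oj];
  const double hsp = y[ohsp], jp = y[ojp];
  const double mL = y[omL], hL = y[ohL], hLp = y[ohLp];
  const double a = y[oa], iF = y[oiF], iS = y[oiS];
  const double ap = y[oap], iFp = y[oiFp], iSp = y[oiSp];
  const double d = y[od], ff = y[off_], fs = y[ofs];
  const double fcaf = y[ofcaf], fcas = y[ofcas], jca = y[ojca], nca = y[onca];
  const double ffp = y[offp], fcafp = y[ofcafp];
  const double xrf = y[oxrf], xrs = y[oxrs], xs1 = y[oxs1], xs2 = y[oxs2];
  const double xk1 = y[oxk1];
  const double Jrelnp = y[oJrelnp], Jrelp = y[oJrelp], CaMKt = y[oCaMKt];

  const double vfrt = v * FRT;
  const double vffrt = v * F * FRT;
  const double ENa = (1.0 / FRT) * fast_log(nao / nai);
  const double EK = (1.0 / FRT) * fast_log(ko / ki);
  const double EKs = (1.0 / FRT) * fast_log((ko + PKNa * nao) / (ki + PKNa * nai));

  // CaMK (HF scales the active fraction)
  const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  const double CaMKa = p[qCamkScale] * (CaMKb + CaMKt);
  const double dCaMKt = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
  const double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

  // --- INa / INaL --------------------------------------------------------
  const double h = 0.99 * hf + 0.01 * hs;
  const double hp = 0.99 * hf + 0.01 * hsp;
  const double m3 = cube(m);
  const double INa = p[qGNa] * (v - ENa) * m3 *
                     ((1.0 - fphos) * h * j + fphos * hp * jp);
  const double INaL = p[qGNaL] * (v - ENa) * mL *
                      ((1.0 - fphos) * hL + fphos * hLp);

  // --- Ito ---------------------------------------------------------------
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double i_gate = AiF * iF + AiS * iS;
  const double ip = AiF * iFp + AiS * iSp;
  const double Ito = p[qGto] * (v - EK) *
                     ((1.0 - fphos) * a * i_gate + fphos * ap * ip);

  // --- ICaL / ICaNa / ICaK ------------------------------------------------
  const double Aff = 0.6, Afs = 0.4;
  const double f = Aff * ff + Afs * fs;
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca = Afcaf * fcaf + Afcas * fcas;
  const double fp = Aff * ffp + Afs * fs;
  const double fcap = Afcaf * fcafp + Afcas * fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = jca * 1.0;
  const double anca = 1.0 / (k2n / km2n + sqr(sqr(1.0 + Kmn / cass)));
  const double e1v = vd[OV_E1V], e2v = vd[OV_E2V];
  const double de2 = (std::fabs(e2v - 1.0) < 1e-9) ? 1e-9 : (e2v - 1.0);
  const double de1 = (std::fabs(e1v - 1.0) < 1e-9) ? 1e-9 : (e1v - 1.0);
  const double PhiCaL = 4.0 * vffrt * (cass * e2v - 0.341 * cao) / de2;
  const double PhiCaNa = vffrt * 0.75 * (nass * e1v - nao) / de1;
  const double PhiCaK = vffrt * 0.75 * (kss * e1v - ko) / de1;
  const double PCa = p[qPCa];
  const double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
  const double gate_p = d * (fp * (1.0 - nca) + jca * fcap * nca);
  const double gmix = (1.0 - fphos) * gate_np + fphos * 1.1 * gate_p;
  const double ICaL = PCa * PhiCaL * gmix;
  const double ICaNa = 0.00125 * PCa * PhiCaNa * gmix;
  const double ICaK = 3.574e-4 * PCa * PhiCaK * gmix;

  // --- IKr / IKs / IK1 ----------------------------------------------------
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double xr = Axrf * xrf + (1.0 - Axrf) * xrs;
  const double IKr = p[qGKr] * std::sqrt(ko / 5.4) * xr * vd[OV_RKR] * (v - EK);
  const double KsCa = do_step ? ksca_look(cai)
                              : 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double IKs = p[qGKs] * KsCa * xs1 * xs2 * (v - EKs);
  const double IK1 = p[qGK1] * std::sqrt(ko) * vd[OV_RK1] * xk1 * (v - EK);

  // --- INaCa (i and ss components) ---------------------------------------
  const double hca = vd[OV_HCA], hna = vd[OV_HNA];
  const double h7_ = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
  const double h8_ = nao / (kna3 * hna * h7_);
  const double h9_ = 1.0 / h7_;
  const double h10_ = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
  const double h11_ = nao * nao / (h10_ * kna1 * kna2);
  const double h12_ = 1.0 / h10_;
  const double k1_ = h12_ * cao * kcaon;
  const double k2_ = kcaoff;
  const double k3p_ = h9_ * wca;
  const double k3pp = h8_ * wnaca;
  const double k3_ = k3p_ + k3pp;
  const double k5_ = kcaoff;
  const double k8_ = h8_ * h11_ * wna;
  auto ncx = [&](double na_c, double ca_c) {
    const double h1 = 1.0 + na_c / kna3 * (1.0 + hna);
    const double h2 = (na_c * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + na_c / kna1 * (1.0 + na_c / kna2);
    const double h5 = na_c * na_c / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double k4p_ = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4_ = k4p_ + k4pp;
    const double k6_ = h6 * ca_c * kcaon;
    const double k7_ = h5 * h2 * wna;
    const double x1 = k2_ * k4_ * (k7_ + k6_) + k5_ * k7_ * (k2_ + k3_);
    const double x2 = k1_ * k7_ * (k4_ + k5_) + k4_ * k6_ * (k1_ + k8_);
    const double x3 = k1_ * k3_ * (k7_ + k6_) + k8_ * k6_ * (k2_ + k3_);
    const double x4 = k2_ * k8_ * (k4_ + k5_) + k3_ * k5_ * (k1_ + k8_);
    const double s = x1 + x2 + x3 + x4;
    const double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    const double allo = 1.0 / (1.0 + sqr(KmCaAct / ca_c));
    const double JncxNa = 3.0 * (E4 * k7_ - E1 * k8_) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2_ - E1 * k1_;
    return allo * (JncxNa + 2.0 * JncxCa);
  };
  const double INaCa_i = 0.8 * p[qGncx] * ncx(nai, cai);
  const double INaCa_ss = 0.2 * p[qGncx] * ncx(nass, cass);

  // --- INaK ----------------------------------------------------------------
  const double Knai = vd[OV_KNAI], Knao = vd[OV_KNAO];
  const double P = eP / (1.0 + H_ / Khp + nai / Knap + ki / Kxkur);
  const double dennai = cube(1.0 + nai / Knai) + sqr(1.0 + ki / Kki) - 1.0;
  const double dennao = cube(1.0 + nao / Knao) + sqr(1.0 + ko / Kko) - 1.0;
  const double a1 = k1p * cube(nai / Knai) / dennai;
  const double b1 = k1m * MgADP;
  const double a2 = k2p;
  const double b2 = k2m * cube(nao / Knao) / dennao;
  const double a3 = k3p_n * sqr(ko / Kko) / dennao;
  const double b3 = k3m * P * H_ / (1.0 + MgATP / Kmgatp);
  const double a4 = k4p_n * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
  const double b4 = k4m * sqr(ki / Kki) / dennai;
  const double x1n = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
  const double x2n = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
  const double x3n = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
  const double x4n = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a4;
  const double sn = x1n + x2n + x3n + x4n;
  const double JnakNa = 3.0 * (x1n * a3 - x2n * b3) / sn;
  const double JnakK = 2.0 * (x4n * b1 - x3n * a1) / sn;
  const double INaK = p[qPnak] * (JnakNa + JnakK);

  // --- background and pump currents ----------------------------------------
  const double IKb = p[qGKb] * vd[OV_XKB] * (v - EK);
  const double INab = p[qPNab] * vffrt * (nai * e1v - nao) / de1;
  const double ICab = p[qPCab] * 4.0 * vffrt * (cai * e2v - 0.341 * cao) / de2;
  const double IpCa = p[qGpCa] * cai / (0.0005 + cai);

  // --- diffusion fluxes ----------------------------------------------------
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // --- SR release ----------------------------------------------------------
  const double bt = 4.75;
  const double ICaL_ca = PCa * PhiCaL * gmix;  // Ca component drives release
  const double inv_cajsr = 1.0 / cajsr;
  const double ec_r = p[qJrelEc50] * inv_cajsr;
  const double ec2 = sqr(ec_r), ec4 = sqr(ec2), ec8 = sqr(ec4);
  const double relgate = 1.0 / (1.0 + ec8);
  double Jrel_inf = p[qJrelScale] * 0.5 * bt * (-ICaL_ca) * relgate;
  double tau_rel = bt / (1.0 + 0.0123 * inv_cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt;
  double Jrel_infp = p[qJrelScale] * 0.5 * btp * (-ICaL_ca) * relgate;
  double tau_relp = btp / (1.0 + 0.0123 * inv_cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  const double Jrel = (1.0 - fphos) * Jrelnp + fphos * Jrelp;

  // --- SERCA uptake and leak ----------------------------------------------
  const double Jupnp = p[qJupBase] * cai / (cai + 0.00092);
  const double Jupp = 2.75 * p[qJupBase] * cai / (cai + 0.00092 - 0.00017);
  const double Jleak = p[qLeakBase] * cansr / 15.0;
  const double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  // --- buffers -------------------------------------------------------------
  const double cmdnmax = p[qCmdnMax], kmcmdn = 0.00238;
  const double trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;

  const double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs +
                      IK1 + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab;

  const double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
                          (F * vmyo) +
                      JdiffNa * vss / vmyo;
  const double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa;
  const double dki = -(Ito + IKr + IKs + IK1 + IKb - Istim - 2.0 * INaK) * Acap /
                         (F * vmyo) +
                     JdiffK * vss / vmyo;
  const double dkss = -ICaK * Acap / (F * vss) - JdiffK;
  const double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / sqr(kmcmdn + cai) +
                             trpnmax * kmtrpn / sqr(kmtrpn + cai));
  const double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                                  (2.0 * F * vmyo) -
                              Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  const double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / sqr(KmBSR + cass) +
                              BSLmax * KmBSL / sqr(KmBSL + cass));
  const double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * F * vss) +
                                Jrel * vjsr / vss - Jdiff);
  const double dcansr = Jup - Jtr * vjsr / vnsr;
  const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / sqr(kmcsqn + cajsr));
  const double dcajsr = Bcajsr * (Jtr - Jrel);

  if (do_step) {
    auto rl = [&](int idx, int g) {
      y[idx] = vd[INF(g)] + (y[idx] - vd[INF(g)]) * vd[TAU(g)];
    };
    rl(om, OV_M);
    rl(ohf, OV_HF);
    rl(ohs, OV_HS);
    rl(oj, OV_J);
    rl(ohsp, OV_HSP);
    rl(ojp, OV_JP);
    rl(omL, OV_ML);
    rl(oa, OV_A);
    rl(oiF, OV_IF);
    rl(oiS, OV_IS);
    rl(oap, OV_AP);
    rl(oiFp, OV_IFP);
    rl(oiSp, OV_ISP);
    rl(od, OV_D);
    rl(off_, OV_FF);
    rl(ofs, OV_FS);
    rl(ofcaf, OV_FCAF);
    rl(ofcas, OV_FCAS);
    rl(ojca, OV_JCA);
    rl(offp, OV_FFP);
    rl(ofcafp, OV_FCAFP);
    rl(oxrf, OV_XRF);
    rl(oxrs, OV_XRS);
    rl(oxs1, OV_XS1);
    rl(oxs2, OV_XS2);
    rl(oxk1, OV_XK1);
    const double ehl = em(dt / p[qThL]);
    y[ohL] = vd[OV_HLINF] + (hL - vd[OV_HLINF]) * ehl;
    const double ehlp = em(dt / (3.0 * p[qThL]));
    y[ohLp] = vd[OV_HLPINF] + (hLp - vd[OV_HLPINF]) * ehlp;
    // linear relaxations: exact update
    const double nca_inf = anca * k2n / km2n;
    y[onca] = nca_inf + (nca - nca_inf) * em(km2n * dt);
    y[oJrelnp] = Jrel_inf + (Jrelnp - Jrel_inf) * em(dt / tau_rel);
    y[oJrelp] = Jrel_infp + (Jrelp - Jrel_infp) * em(dt / tau_relp);
    y[oCaMKt] += dt * dCaMKt;
    y[onai] += dt * dnai;
    y[onass] += dt * dnass;
    y[oki] += dt * dki;
    y[okss] += dt * dkss;
    y[ocai] += dt * dcai;
    y[ocass] += dt * dcass;
    y[ocansr] += dt * dcansr;
    y[ocajsr] += dt * dcajsr;
    if (y[ocai] < 1e-9) y[ocai] = 1e-9;
    if (y[ocass] < 1e-9) y[ocass] = 1e-9;
  } else {
    dy[oV] = -(Itot - Istim);
    dy[onai] = dnai;
    dy[onass] = dnass;
    dy[oki] = dki;
    dy[okss] = dkss;
    dy[ocai] = dcai;
    dy[ocass] = dcass;
    dy[ocansr] = dcansr;
    dy[ocajsr] = dcajsr;
    auto g = [&](int idx, int slot) {
      dy[idx] = (vd[INF(slot)] - y[idx]) / vd[TAU(slot)];
    };
    g(om, OV_M);
    g(ohf, OV_HF);
    g(ohs, OV_HS);
    g(oj, OV_J);
    g(ohsp, OV_HSP);
    g(ojp, OV_JP);
    g(omL, OV_ML);
    g(oa, OV_A);
    g(oiF, OV_IF);
    g(oiS, OV_IS);
    g(oap, OV_AP);
    g(oiFp, OV_IFP);
    g(oiSp, OV_ISP);
    g(od, OV_D);
    g(off_, OV_FF);
    g(ofs, OV_FS);
    g(ofcaf, OV_FCAF);
    g(ofcas, OV_FCAS);
    g(ojca, OV_JCA);
    g(offp, OV_FFP);
    g(ofcafp, OV_FCAFP);
    g(oxrf, OV_XRF);
    g(oxrs, OV_XRS);
    g(oxs1, OV_XS1);
    g(oxs2, OV_XS2);
    g(oxk1, OV_XK1);
    dy[ohL] = (vd[OV_HLINF] - hL) / p[qThL];
    dy[ohLp] = (vd[OV_HLPINF] - hLp) / (3.0 * p[qThL]);
    dy[onca] = anca * k2n - nca * km2n;
    dy[oJrelnp] = (Jrel_inf - Jrelnp) / tau_rel;
    dy[oJrelp] = (Jrel_infp - Jrelp) / tau_relp;
    dy[oCaMKt] = dCaMKt;
  }
  return Itot;
}

double ord_step(double* y, const double* p, double Istim, double dt) {
  return ord_core(y, p, Istim, dt, nullptr, true);
}
double ord_rhs(const double* y, const double* p, double Istim, double* dy) {
  return ord_core(const_cast<double*>(y), p, Istim, 0.0, dy, false);
}

#undef INF
#undef TAU

}  // namespace hfs
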