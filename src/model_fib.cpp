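// MacCannell active ventricular fibroblast (2007 lineage): a time- and
// voltage-dependent K+ current (I_Kv), an inward-rectifier K+ current (I_K1),
// a Na+/K+ pump (I_NaK) and a background Na+ current (I_bNa).  Expressed per
// unit membrane capacitance (uA/uF); C_m = 6.3 pF carried as a parameter so
// absolute currents can be recovered.  Intracellular Na+/K+ are held at the
// published values, which makes the ~-49.6 mV rest a true equilibrium of the
// four-current membrane model.

#include "models.h"
#include <cmath>

namespace hfs {

enum { fV = 0, fr, fs };
enum {
  gKv = 0, gK1, gbNa, INaKmax, KmK, KmNa, fKo, fNao, fKi, fNai, fCm
};

static const double RTF = 8314.0 * 310.0 / 96485.0;  // mV

void fib_default_params(double* p) {
  p[gKv] = 0.25;      // nS/pF
  p[gK1] = 0.4822;    // nS/pF
  p[gbNa] = 0.0095;   // nS/pF
  p[INaKmax] = 2.002; // pA/pF
  p[KmK] = 1.0;       // mM
  p[KmNa] = 11.0;     // mM
  p[fKo] = 5.3581;    // mM
  p[fNao] = 130.011;  // mM
  p[fKi] = 129.4349;  // mM
  p[fNai] = 8.5547;   // mM
  p[fCm] = 6.3;       // pF
}

void fib_init(double* y) {
  y[fV] = -49.6;
  y[fr] = 0.0;
  y[fs] = 1.0;
}

void fib_currents(const double* y, const double* p, double* out4) {
  const double v = y[fV];
  const double EK = RTF * std::log(p[fKo] / p[fKi]);
  const double ENa = RTF * std::log(p[fNao] / p[fNai]);
  const double IKv = p[gKv] * y[fr] * y[fs] * (v - EK);
  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (v - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (v - EK + 100.0)) +
                      std::exp(0.1 * (v - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (v - EK)));
  const double IK1 = p[gK1] * aK1 / (aK1 + bK1) * (v - EK);
  const double nai15 = std::pow(p[fNai], 1.5);
  const double INaK = p[INaKmax] * (p[fKo] / (p[fKo] + p[KmK])) *
                      (nai15 / (nai15 + std::pow(p[KmNa], 1.5))) *
                      (v + 150.0) / (v + 200.0);
  const double IbNa = p[gbNa] * (v - ENa);
  out4[0] = IKv;
  out4[1] = IK1;
  out4[2] = INaK;
  out4[3] = IbNa;
}

static double fib_core(double* y, const double* p, double Istim, double dt,
                       double* dy, bool do_step) {
  const double v = y[fV];
  double cur[4];
  fib_currents(y, p, cur);
  const double Itot = cur[0] + cur[1] + cur[2] + cur[3];

  const double rinf = 1.0 / (1.0 + std::exp(-(v + 20.0) / 11.0));
  const double taur = 20.3 + 138.0 * std::exp(-std::pow((v + 20.0) / 25.9, 2));
  const double sinf = 1.0 / (1.0 + std::exp((v + 23.0) / 7.0));
  const double taus = 1574.0 + 5268.0 * std::exp(-std::pow((v + 23.0) / 22.7, 2));

  if (do_step) {
    y[fr] = rinf + (y[fr] - rinf) * std::exp(-dt / taur);
    y[fs] = sinf + (y[fs] - sinf) * std::exp(-dt / taus);
  } else {
    dy[fV] = -(Itot - Istim);
    dy[fr] = (rinf - y[fr]) / taur;
    dy[fs] = (sinf - y[fs]) / taus;
  }
  return Itot;
}

double fib_step(double* y, const double* p, double Istim, double dt) {
  return fib_core(y, p, Istim, dt, nullptr, true);
}
double fib_rhs(const double* y, const double* p, double Istim, double* dy) {
  return fib_core(const_cast<double*>(y), p, Istim, 0.0, dy, false);
}

}  // namespace hfs
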