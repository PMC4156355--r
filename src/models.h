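#pragma once

// Membrane-kinetics kernels for the three cell types used in the strand:
//   GPB  - Grandi/Pasqualini/Bers human ventricular myocyte (2010 lineage),
//          endo/epi variants, extended with a Maltsev/Undrovinas-style late
//          Na+ current so heart-failure scaling of I_NaL / tau_hL applies.
//   ORD  - O'Hara/Rudy human ventricular myocyte (2011), endo/M/epi variants.
//   FIB  - MacCannell active ventricular fibroblast (2007), four currents,
//          C_m = 6.3 pF, expressed per unit capacitance (uA/uF).
//
// Transcribed from the published model formulations (public model code of the
// respective papers); state orderings are explicit registries on the R side.
//
// Contract shared by all models:
//   y[0] is V_m (mV) and is NEVER advanced here - the cable solver owns V.
//   *_step  advances gates (exact exponential / Rush-Larsen update) and
//           concentrations (forward Euler) by dt at frozen V, and returns
//           I_ion (uA/uF) evaluated at the pre-step state.
//   *_rhs   writes pure derivatives dy[1..] (dy[0] = -I_ion) and returns
//           I_ion; used by the stiff-solver reference integration.

#include <cstdint>
#include <cmath>

namespace hfs {

// fast natural log for positive, finite inputs (atanh-series on the
// mantissa; relative error < 1e-10); used for Nernst potentials and
// log-grid table lookups in the fixed-step kernels
inline double fast_log(double x) {
  union { double d; std::uint64_t i; } u;
  u.d = x;
  int e = (int)((u.i >> 52) & 0x7ff) - 1023;
  u.i = (u.i & 0xfffffffffffffULL) | 0x3ff0000000000000ULL;  // mantissa in [1,2)
  double m = u.d;
  if (m > 1.4142135623730951) { m *= 0.5; e += 1; }
  const double f = (m - 1.0) / (m + 1.0);
  const double f2 = f * f;
  const double s = 2.0 * f *
      (1.0 + f2 * (1.0 / 3.0 + f2 * (0.2 + f2 * (1.0 / 7.0 +
       f2 * (1.0 / 9.0 + f2 / 11.0)))));
  return s + e * 0.6931471805599453;
}

enum CellClass { ENDO = 1, MID = 2, EPI = 3, FIBRO = 4 };
// M_PAS is a passive linear membrane (I_ion = g*(V - E), params p = {g, E});
// with g = 0 the cable reduces to pure diffusion.  Used by numerical oracles.
enum ModelId { M_PAS = 0, M_GPB = 1, M_ORD = 2, M_FIB = 3 };

constexpr int GPB_NSTATES = 41;
constexpr int ORD_NSTATES = 41;
constexpr int FIB_NSTATES = 3;
constexpr int MAX_NSTATES = 41;

constexpr int GPB_NPARAMS = 40;
constexpr int ORD_NPARAMS = 21;
constexpr int FIB_NPARAMS = 11;
constexpr int MAX_NPARAMS = 40;

void gpb_init(double* y);
void gpb_default_params(int cell_class, double* p);
double gpb_step(double* y, const double* p, double Istim, double dt);
double gpb_rhs(const double* y, const double* p, double Istim, double* dy);

void ord_init(double* y);
void ord_default_params(int cell_class, double* p);
double ord_step(double* y, const double* p, double Istim, double dt);
double ord_rhs(const double* y, const double* p, double Istim, double* dy);

void fib_init(double* y);
void fib_default_params(double* p);
double fib_step(double* y, const double* p, double Istim, double dt);
double fib_rhs(const double* y, const double* p, double Istim, double* dy);
// component currents {I_Kv, I_K1, I_NaK, I_bNa} at the current state
void fib_currents(const double* y, const double* p, double* out4);

inline int model_nstates(int m) {
  if (m == M_PAS) return 1;
  return m == M_GPB ? GPB_NSTATES : (m == M_ORD ? ORD_NSTATES : FIB_NSTATES);
}

}  // namespace hfs
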