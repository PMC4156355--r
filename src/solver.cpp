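// Operator-split monodomain solver on a 1D strand with per-element diffusion
// and sealed (no-flux) ends.  Each time step: (i) explicit ionic sub-step at
// every node (Rush-Larsen gates, forward-Euler concentrations) giving I_ion;
// (ii) explicit membrane update V* = V + dt*(-I_ion + I_stim); (iii) implicit
// (backward Euler) diffusion solve of the tridiagonal system arising from the
// second-difference stencil with per-element D — unconditionally stable.
//
// Per-node upstroke markers (time and value of max dV/dt, max/min V) are
// tracked at solver resolution from `track_from` onward so conduction times
// do not depend on the trace sampling interval.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include "models.h"

using namespace Rcpp;
using namespace hfs;

static inline double step_dispatch(int model, double* y, const double* p,
                                   double Istim, double dt) {
  switch (model) {
    case M_PAS: return p[0] * (y[0] - p[1]);
    case M_GPB: return gpb_step(y, p, Istim, dt);
    case M_ORD: return ord_step(y, p, Istim, dt);
    default:    return fib_step(y, p, Istim, dt);
  }
}

// [[Rcpp::export]]
int model_nstates_cpp(int model) { return model_nstates(model); }

// [[Rcpp::export]]
NumericVector model_init_cpp(int model) {
  NumericVector y(model_nstates(model));
  if (model == M_PAS) y[0] = 0.0;
  else if (model == M_GPB) gpb_init(y.begin());
  else if (model == M_ORD) ord_init(y.begin());
  else fib_init(y.begin());
  return y;
}

// [[Rcpp::export]]
NumericVector model_default_params_cpp(int model, int cell_class) {
  if (model == M_PAS) {
    NumericVector p = NumericVector::create(0.0, 0.0);
    return p;
  }
  if (model == M_GPB) {
    NumericVector p(GPB_NPARAMS);
    gpb_default_params(cell_class, p.begin());
    return p;
  } else if (model == M_ORD) {
    NumericVector p(ORD_NPARAMS);
    ord_default_params(cell_class, p.begin());
    return p;
  }
  NumericVector p(FIB_NPARAMS);
  fib_default_params(p.begin());
  return p;
}

// [[Rcpp::export]]
List cell_rhs_cpp(int model, NumericVector y, NumericVector params,
                  double Istim) {
  NumericVector dy(y.size());
  double Iion;
  if (model == M_PAS) {
    Iion = params[0] * (y[0] - params[1]);
    dy[0] = -(Iion - Istim);
    return List::create(_["dy"] = dy, _["Iion"] = Iion);
  }
  if (model == M_GPB) Iion = gpb_rhs(y.begin(), params.begin(), Istim, dy.begin());
  else if (model == M_ORD) Iion = ord_rhs(y.begin(), params.begin(), Istim, dy.begin());
  else Iion = fib_rhs(y.begin(), params.begin(), Istim, dy.begin());
  return List::create(_["dy"] = dy, _["Iion"] = Iion);
}

// [[Rcpp::export]]
List cell_step_cpp(int model, NumericVector y, NumericVector params,
                   double Istim, double dt) {
  NumericVector yn = clone(y);
  const double Iion = step_dispatch(model, yn.begin(), params.begin(), Istim, dt);
  yn[0] += dt * (-Iion + Istim);  // single-cell membrane update
  return List::create(_["y"] = yn, _["Iion"] = Iion);
}

// [[Rcpp::export]]
NumericVector fib_currents_cpp(NumericVector y, NumericVector params) {
  NumericVector out(4);
  fib_currents(y.begin(), params.begin(), out.begin());
  out.attr("names") = CharacterVector::create("I_Kv", "I_K1", "I_NaK", "I_bNa");
  return out;
}

// [[Rcpp::export]]
List strand_solve_cpp(IntegerVector model, NumericMatrix state0,
                      NumericMatrix params, NumericVector D_elem, double dx,
                      double dt, double t0, double duration,
                      IntegerVector stim_nodes, NumericVector stim_times,
                      double stim_amp, double stim_dur,
                      double sample_interval, double track_from,
                      bool record_cai, NumericVector cap_scale) {
  const int n = model.size();
  if (state0.ncol() != n || params.ncol() != n)
    stop("state/params column count must equal number of nodes");
  if (n > 1 && D_elem.size() != n - 1)
    stop("D_elem must have length n_nodes - 1");
  const long nsteps = (long)std::llround(duration / dt);
  const int sample_every = std::max(1, (int)std::llround(sample_interval / dt));
  const int nsamp = (int)(nsteps / sample_every) + 1;

  // local state copy (column-major, MAX_NSTATES stride)
  std::vector<double> Y(state0.begin(), state0.end());
  const int sy = state0.nrow();
  std::vector<const double*> P(n);
  for (int i = 0; i < n; ++i) P[i] = &params(0, i);

  // Thomas prefactorization of (I - dt*L)
  std::vector<double> sub(n, 0.0), diag(n, 1.0), sup(n, 0.0), cp(n, 0.0),
      invden(n, 0.0), rhs(n, 0.0);
  if (n > 1 && cap_scale.size() != n)
    stop("cap_scale must have one entry per node");
  if (n > 1) {
    // row i of the diffusion operator is scaled by cap_scale[i] (membrane
    // capacitance of the reference myocyte over the node's capacitance):
    // low-capacitance nodes (fibroblasts) charge more easily per unit of
    // their own capacitance
    std::vector<double> r(n - 1);
    for (int e = 0; e < n - 1; ++e) r[e] = dt * D_elem[e] / (dx * dx);
    for (int i = 0; i < n; ++i) {
      const double rl = ((i > 0) ? r[i - 1] : 0.0) * cap_scale[i];
      const double rr = ((i < n - 1) ? r[i] : 0.0) * cap_scale[i];
      sub[i] = -rl;
      diag[i] = 1.0 + rl + rr;
      sup[i] = -rr;
    }
    cp[0] = sup[0] / diag[0];
    invden[0] = 1.0 / diag[0];
    for (int i = 1; i < n; ++i) {
      const double den = diag[i] - sub[i] * cp[i - 1];
      invden[i] = 1.0 / den;
      cp[i] = sup[i] * invden[i];
    }
  }

  NumericVector times(nsamp);
  NumericMatrix vm(nsamp, n);
  NumericMatrix cai;
  if (record_cai) cai = NumericMatrix(nsamp, n);
  std::vector<int> cai_idx(n);
  for (int i = 0; i < n; ++i)
    cai_idx[i] = model[i] == M_GPB ? 38 : (model[i] == M_ORD ? 5 : -1);

  std::vector<double> up_t(n, NA_REAL), up_dvdt(n, -1e300), vmax(n, -1e300),
      vmin(n, 1e300);

  std::vector<bool> is_stim(n, false);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    const int s = stim_nodes[k];
    if (s < 0 || s >= n) stop("stimulus node out of range");
    is_stim[s] = true;
  }
  std::vector<double> stim_t(stim_times.begin(), stim_times.end());
  std::sort(stim_t.begin(), stim_t.end());
  std::vector<int> mdl(model.begin(), model.end());
  size_t next_stim = 0;

  // record initial sample
  int samp = 0;
  times[samp] = t0;
  for (int i = 0; i < n; ++i) {
    vm(samp, i) = Y[(size_t)i * sy];
    if (record_cai)
      cai(samp, i) = cai_idx[i] >= 0 ? Y[(size_t)i * sy + cai_idx[i]] : NA_REAL;
  }
  ++samp;

  std::vector<double> vold(n);
  for (long s = 0; s < nsteps; ++s) {
    const double t = t0 + s * dt;
    // stimulus active this step? (stim_t sorted; window [t_k, t_k + dur))
    while (next_stim < stim_t.size() && t >= stim_t[next_stim] + stim_dur)
      ++next_stim;
    const double amp =
        (next_stim < stim_t.size() && t >= stim_t[next_stim]) ? stim_amp : 0.0;
    for (int i = 0; i < n; ++i) {
      double* y = &Y[(size_t)i * sy];
      vold[i] = y[0];
      const double Ist = (amp != 0.0 && is_stim[i]) ? amp : 0.0;
      const double Iion = step_dispatch(mdl[i], y, P[i], Ist, dt);
      y[0] += dt * (-Iion + Ist);
    }
    if (n > 1) {
      // implicit diffusion: Thomas solve
      rhs[0] = Y[0] * invden[0];
      for (int i = 1; i < n; ++i)
        rhs[i] = (Y[(size_t)i * sy] - sub[i] * rhs[i - 1]) * invden[i];
      Y[(size_t)(n - 1) * sy] = rhs[n - 1];
      for (int i = n - 2; i >= 0; --i)
        Y[(size_t)i * sy] = rhs[i] - cp[i] * Y[(size_t)(i + 1) * sy];
    }
    const double tnew = t + dt;
    for (int i = 0; i < n; ++i) {
      const double v = Y[(size_t)i * sy];
      if (!std::isfinite(v)) {
        stop("non-finite membrane potential at node %d (1-based), t = %.3f ms",
             i + 1, tnew);
      }
      if (tnew >= track_from) {
        const double dvdt = (v - vold[i]) / dt;
        if (dvdt > up_dvdt[i]) {
          up_dvdt[i] = dvdt;
          up_t[i] = tnew;
        }
        if (v > vmax[i]) vmax[i] = v;
        if (v < vmin[i]) vmin[i] = v;
      }
    }
    if ((s + 1) % sample_every == 0 && samp < nsamp) {
      times[samp] = tnew;
      for (int i = 0; i < n; ++i) {
        vm(samp, i) = Y[(size_t)i * sy];
        if (record_cai)
          cai(samp, i) = cai_idx[i] >= 0 ? Y[(size_t)i * sy + cai_idx[i]] : NA_REAL;
      }
      ++samp;
    }
  }

  NumericMatrix state_out(sy, n);
  std::copy(Y.begin(), Y.end(), state_out.begin());
  List out = List::create(
      _["times"] = times, _["vm"] = vm, _["state"] = state_out,
      _["upstroke_time"] = wrap(up_t), _["dvdt_max"] = wrap(up_dvdt),
      _["vmax"] = wrap(vmax), _["vmin"] = wrap(vmin));
  if (record_cai) out["cai"] = cai;
  return out;
}
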