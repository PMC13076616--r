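#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Passive branched-cable solver, backward Euler on the tree (Hines ordering:
// parent index < child index, root = segment 0). Units: nF, uS, mV, ms, nA.
// Synaptic drive is supplied on the (coarser) stimulus time base and
// linearly interpolated onto the voltage step. An optional Hodgkin-Huxley
// style Na/K pair at the recorded (somatic) segment enables spiking; gates
// advance by exponential Euler, conductances enter the implicit solve.

static inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// [[Rcpp::export]]
NumericVector cpp_cable_solve(IntegerVector parent, NumericVector cm_nF,
                              NumericVector gpas_uS, NumericVector gax_uS,
                              double e_rest, IntegerVector syn_seg,
                              NumericVector syn_e, NumericMatrix g_syn,
                              double dt_stim, double dt_v, int n_steps,
                              int record, bool hh, double gna_uS, double gk_uS) {
  int n = parent.size();
  int nsyn = syn_seg.size();
  int n_stim = g_syn.nrow();
  std::vector<double> V(n, e_rest), base_d(n), d(n), rhs(n);
  for (int i = 0; i < n; ++i)
    base_d[i] = cm_nF[i] / dt_v + gpas_uS[i] + gax_uS[i];
  for (int i = 1; i < n; ++i) base_d[parent[i]] += gax_uS[i];

  const double e_na = 55.0, e_k = -72.0;
  double m = 0.05, h = 0.6, ngate = 0.32; // near rest for u ~ 0

  NumericVector out(n_steps + 1);
  out[0] = V[record];

  for (int step = 1; step <= n_steps; ++step) {
    double t = step * dt_v;
    // interpolate synaptic conductances
    double pos = t / dt_stim;
    int i0 = (int)std::floor(pos);
    double frac = pos - i0;
    if (i0 >= n_stim - 1) { i0 = n_stim - 1; frac = 0.0; }

    for (int i = 0; i < n; ++i) {
      d[i] = base_d[i];
      rhs[i] = cm_nF[i] / dt_v * V[i] + gpas_uS[i] * e_rest;
    }
    for (int j = 0; j < nsyn; ++j) {
      double g = (frac == 0.0) ? g_syn(i0, j)
                               : (1.0 - frac) * g_syn(i0, j) + frac * g_syn(i0 + 1, j);
      if (g <= 0.0) continue;
      int s = syn_seg[j];
      d[s] += g;
      rhs[s] += g * syn_e[j];
    }
    if (hh) {
      double u = V[record] + 60.0; // classic convention: rest at 0
      double am = 0.1 * vtrap(25.0 - u, 10.0);
      double bm = 4.0 * std::exp(-u / 18.0);
      double ah = 0.07 * std::exp(-u / 20.0);
      double bh = 1.0 / (std::exp((30.0 - u) / 10.0) + 1.0);
      double an = 0.01 * vtrap(10.0 - u, 10.0);
      double bn = 0.125 * std::exp(-u / 80.0);
      double taum = 1.0 / (am + bm), tauh = 1.0 / (ah + bh),
             taun = 1.0 / (an + bn);
      m += (am * taum - m) * (1.0 - std::exp(-dt_v / taum));
      h += (ah * tauh - h) * (1.0 - std::exp(-dt_v / tauh));
      ngate += (an * taun - ngate) * (1.0 - std::exp(-dt_v / taun));
      double gna = gna_uS * m * m * m * h;
      double gk = gk_uS * ngate * ngate * ngate * ngate;
      d[record] += gna + gk;
      rhs[record] += gna * e_na + gk * e_k;
    }
    // Hines elimination: leaves toward root
    for (int i = n - 1; i >= 1; --i) {
      double f = gax_uS[i] / d[i];
      int p = parent[i];
      d[p] -= gax_uS[i] * f;
      rhs[p] += rhs[i] * f;
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] + gax_uS[i] * V[parent[i]]) / d[i];
    if (!std::isfinite(V[record]))
      stop("compartmental solver diverged (non-finite voltage)");
    out[step] = V[record];
  }
  return out;
}
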