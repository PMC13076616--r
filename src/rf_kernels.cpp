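#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 2-D Gaussian receptive-field weight as used throughout: the size parameters
// are the distances at which the profile falls to half maximum, i.e.
// w = exp(-[x_th * sqrt(ln 2) / size_x]^2 - [y_th * sqrt(ln 2) / size_y]^2)
// with (x_th, y_th) the centered, rotated pixel coordinates.
static inline double gauss_rf(double dx, double dy, double ct, double st,
                              double sx, double sy) {
  const double L2 = 0.6931471805599453; // ln 2
  double xt = dx * ct + dy * st;
  double yt = -dx * st + dy * ct;
  double ex = xt * xt * L2 / (sx * sx) + yt * yt * L2 / (sy * sy);
  if (ex > 40.0) return 0.0;
  return std::exp(-ex);
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_field(NumericVector xs, NumericVector ys,
                              double cx, double cy, double sx, double sy,
                              double theta) {
  int nx = xs.size(), ny = ys.size();
  double ct = std::cos(theta), st = std::sin(theta);
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out(i, j) = gauss_rf(xs[i] - cx, ys[j] - cy, ct, st, sx, sy);
  return out;
}

// Profile for moving-bar stimuli. Pixels are supplied pre-sorted by their
// projection s onto the motion axis; u is the perpendicular projection used
// to clip the bar to its finite height. Returns the cumulative Gaussian mass
// below each sorted projection (restricted to the bar's height window) and
// the full-arena normalizer so that full-field illumination gives area 1.
// [[Rcpp::export]]
List cpp_bar_profile(NumericVector px, NumericVector py, NumericVector pu,
                     double cx, double cy, double sx, double sy, double theta,
                     double u_lo, double u_hi) {
  int n = px.size();
  double ct = std::cos(theta), st = std::sin(theta);
  double rcut = 6.0 * std::max(sx, sy);
  double r2 = rcut * rcut;
  NumericVector csum(n + 1);
  double denom = 0.0, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - cx, dy = py[i] - cy;
    double w = 0.0;
    if (dx * dx + dy * dy <= r2) w = gauss_rf(dx, dy, ct, st, sx, sy);
    denom += w;
    if (pu[i] >= u_lo && pu[i] <= u_hi) acc += w;
    csum[i + 1] = acc;
  }
  return List::create(_["csum"] = csum, _["denom"] = denom);
}

// Windowed sums over the sorted-projection cumulative profile: for each lead
// edge position, the Gaussian mass with lead - width < s <= lead.
// [[Rcpp::export]]
NumericVector cpp_window_sum(NumericVector s_sorted, NumericVector csum,
                             double denom, NumericVector lead, double width) {
  int nt = lead.size();
  NumericVector out(nt);
  if (denom <= 0) return out;
  const double* sb = s_sorted.begin();
  const double* se = s_sorted.end();
  for (int t = 0; t < nt; ++t) {
    int hi = std::upper_bound(sb, se, lead[t]) - sb;
    int lo = std::upper_bound(sb, se, lead[t] - width) - sb;
    out[t] = (csum[hi] - csum[lo]) / denom;
  }
  return out;
}

// Drifting sinusoidal grating: intensity 0.5 + 0.5 sin(k s - omega t), exact
// via the angle-sum identity so it matches a pixel-rendered frame bit-for-bit
// up to floating-point association order.
// [[Rcpp::export]]
NumericVector cpp_grating_area(NumericVector px, NumericVector py,
                               double cx, double cy, double sx, double sy,
                               double theta, double dir, double k,
                               double omega, NumericVector tvec) {
  int n = px.size();
  double ct = std::cos(theta), st = std::sin(theta);
  double cd = std::cos(dir), sd = std::sin(dir);
  double rcut = 6.0 * std::max(sx, sy), r2 = rcut * rcut;
  double A = 0.0, B = 0.0, N = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - cx, dy = py[i] - cy;
    if (dx * dx + dy * dy > r2) continue;
    double w = gauss_rf(dx, dy, ct, st, sx, sy);
    double s = px[i] * cd + py[i] * sd;
    A += w * std::sin(k * s);
    B += w * std::cos(k * s);
    N += w;
  }
  int nt = tvec.size();
  NumericVector out(nt);
  if (N <= 0) return out;
  for (int t = 0; t < nt; ++t) {
    double wt = omega * tvec[t];
    out[t] = 0.5 + 0.5 * (A * std::cos(wt) - B * std::sin(wt)) / N;
  }
  return out;
}

// Per-bar Gaussian mass for 1-D contrast-noise stimulation: bar b covers
// projections in [edges[b], edges[b+1]).
// [[Rcpp::export]]
NumericVector cpp_noise_bar_weights(NumericVector px, NumericVector py,
                                    double cx, double cy, double sx, double sy,
                                    double theta, double dir,
                                    NumericVector edges) {
  int n = px.size(), nb = edges.size() - 1;
  double ct = std::cos(theta), st = std::sin(theta);
  double cd = std::cos(dir), sd = std::sin(dir);
  NumericVector w(nb);
  double denom = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - cx, dy = py[i] - cy;
    double g = gauss_rf(dx, dy, ct, st, sx, sy);
    denom += g;
    double s = px[i] * cd + py[i] * sd;
    int b = std::upper_bound(edges.begin(), edges.end(), s) - edges.begin() - 1;
    if (b >= 0 && b < nb && s >= edges[b]) w[b] += g;
  }
  if (denom > 0) for (int b = 0; b < nb; ++b) w[b] /= denom;
  return w;
}

// First-order receptive-field activation with readily-releasable-pool
// adaptation:
//   RF_t    = (area_t - RF_{t-1}) * dt / rise + RF_{t-1} * adaptation_{t-1}
//   adapt_t = max(0, adaptation_{t-1} - RF_t * dt / decay)
// With adaptation disabled the adaptation term stays at 1.
// [[Rcpp::export]]
List cpp_rf_temporal(NumericVector area, double dt, double rise, double decay,
                     bool adapt_on, int delay_steps) {
  int n = area.size();
  NumericVector rf(n), ad(n);
  double rf_prev = 0.0, ad_prev = 1.0;
  for (int t = 0; t < n; ++t) {
    int ts = t - delay_steps;
    double a = (ts >= 0) ? area[ts] : 0.0;
    double rf_t = (a - rf_prev) * dt / rise + rf_prev * ad_prev;
    double ad_t = adapt_on ? std::max(0.0, ad_prev - rf_t * dt / decay) : 1.0;
    rf[t] = rf_t; ad[t] = ad_t;
    rf_prev = rf_t; ad_prev = ad_t;
  }
  return List::create(_["rf"] = rf, _["adaptation"] = ad);
}

// Short-term depression of release. Default mode: multiplicative depletion by
// the driven release followed by first-order recovery toward a full pool.
// Literal mode reproduces the printed recursion, in which the facilitation
// amplitude and time constant appear inside the depression update.
// [[Rcpp::export]]
List cpp_depression(NumericVector r, double dt, double dep_amp, double dep_tau,
                    bool literal, double fac_amp, double fac_tau) {
  int n = r.size();
  NumericVector out(n), state(n);
  double s = 1.0;
  for (int t = 0; t < n; ++t) {
    if (literal) {
      double s_prev = s;
      s = s_prev * fac_amp * (1.0 - dep_amp * r[t]);
      s = s * (1.0 - s_prev / (fac_tau / dt));
    } else {
      s = s * (1.0 - dep_amp * r[t]);
      s = s + (1.0 - s) * dt / dep_tau;
    }
    out[t] = r[t] * s;
    state[t] = s;
  }
  return List::create(_["release"] = out, _["state"] = state);
}

// Short-term facilitation: state integrates the driven release, decays with
// tau, is clipped to [0, 1], and multiplies release by 10^state, so the
// amplification factor spans [1, 10].
// [[Rcpp::export]]
List cpp_facilitation(NumericVector r, double dt, double fac_amp,
                      double fac_tau) {
  int n = r.size();
  NumericVector out(n), state(n);
  double f = 0.0;
  for (int t = 0; t < n; ++t) {
    f = fac_amp * r[t] + f;
    f = f - f * dt / fac_tau;
    if (f < 0.0) f = 0.0;
    if (f > 1.0) f = 1.0;
    out[t] = r[t] * std::pow(10.0, f);
    state[t] = f;
  }
  return List::create(_["release"] = out, _["state"] = state);
}
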