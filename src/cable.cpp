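#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 1D monodomain modified Mitchell-Schaeffer cable, operator splitting:
// sub-cycled forward-Euler reaction at dt_ion, Crank-Nicolson diffusion at
// dt_dif, no-flux (mirror) boundaries.  Units: mm, ms, normalized voltage.
//
// The CN system (I - a/2 L) V' = (I + a/2 L) V with a = D*dt/dx^2 and
// L the mirrored second-difference operator is tridiagonal; we factorize
// once per call (Thomas algorithm).

// [[Rcpp::export(name = ".mms_cable_segment")]]
List mms_cable_segment(NumericVector V0, NumericVector h0,
                       double tau_in, double tau_out, double tau_open,
                       double tau_close, double v_gate, double D, double dx,
                       double dt_dif, double dt_ion, double t_total,
                       NumericMatrix stim,       // cols: t_on, dur, node_lo, node_hi (1-based), amp
                       IntegerVector record_nodes, // 1-based; empty = none
                       bool record_all) {
  const int n = V0.size();
  if (h0.size() != n) stop("V0 and h0 must have equal length");
  const int nsub = (int) std::lround(dt_dif / dt_ion);
  if (std::fabs(nsub * dt_ion - dt_dif) > 1e-9)
    stop("dt_ion must divide dt_dif");
  const int nstep = (int) std::ceil(t_total / dt_dif - 1e-9);

  // Thomas factorization of (I - a/2 L); L row i: V[i-1] - 2 V[i] + V[i+1],
  // boundary rows use the mirror ghost: 2 V[1] - 2 V[0] (and symmetric).
  const double a = D * dt_dif / (dx * dx);
  std::vector<double> low(n), diag(n), up(n);
  for (int i = 0; i < n; ++i) {
    diag[i] = 1.0 + a;
    low[i] = up[i] = -0.5 * a;
  }
  up[0] = -a;          // mirror boundary
  low[n - 1] = -a;
  // forward elimination coefficients
  std::vector<double> cp(n), denom(n);
  denom[0] = diag[0];
  cp[0] = up[0] / denom[0];
  for (int i = 1; i < n; ++i) {
    denom[i] = diag[i] - low[i] * cp[i - 1];
    cp[i] = up[i] / denom[i];
  }

  std::vector<double> V(V0.begin(), V0.end()), h(h0.begin(), h0.end());
  std::vector<double> rhs(n), d(n);

  const int nstim = stim.nrow();
  const int nrec = record_nodes.size();
  NumericMatrix trace(record_all || nrec == 0 ? 0 : nstep + 1,
                      record_all ? 0 : nrec);
  NumericMatrix full(record_all ? nstep + 1 : 0, record_all ? n : 0);
  NumericVector times(nstep + 1);

  auto record = [&](int step) {
    times[step] = step * dt_dif;
    if (record_all) {
      for (int i = 0; i < n; ++i) full(step, i) = V[i];
    } else {
      for (int r = 0; r < nrec; ++r) trace(step, r) = V[record_nodes[r] - 1];
    }
  };
  record(0);

  for (int step = 0; step < nstep; ++step) {
    const double t0 = step * dt_dif;
    // reaction substeps
    for (int s = 0; s < nsub; ++s) {
      const double t = t0 + s * dt_ion;
      for (int i = 0; i < n; ++i) {
        const double v = V[i], hh = h[i];
        double dv = hh * v * (v - v_gate) * (1.0 - v) / tau_in
                    - (1.0 - hh) * v / tau_out;
        const double dh = (v <= v_gate) ? (1.0 - hh) / tau_open
                                        : -hh / tau_close;
        V[i] = v + dt_ion * dv;
        h[i] = hh + dt_ion * dh;
        if (h[i] < 0.0) h[i] = 0.0;
        if (h[i] > 1.0) h[i] = 1.0;
      }
      // stimulus currents (applied after the ionic update, same substep)
      for (int k = 0; k < nstim; ++k) {
        const double on = stim(k, 0), dur = stim(k, 1);
        if (t + 1e-9 >= on && t < on + dur - 1e-9) {
          int lo = (int) stim(k, 2) - 1, hi = (int) stim(k, 3) - 1;
          if (lo < 0) lo = 0;
          if (hi >= n) hi = n - 1;
          const double amp = stim(k, 4);
          for (int i = lo; i <= hi; ++i) V[i] += dt_ion * amp;
        }
      }
    }
    // Crank-Nicolson diffusion
    // rhs = (I + a/2 L) V
    rhs[0] = V[0] + 0.5 * a * (2.0 * V[1] - 2.0 * V[0]);
    for (int i = 1; i < n - 1; ++i)
      rhs[i] = V[i] + 0.5 * a * (V[i - 1] - 2.0 * V[i] + V[i + 1]);
    rhs[n - 1] = V[n - 1] + 0.5 * a * (2.0 * V[n - 2] - 2.0 * V[n - 1]);
    d[0] = rhs[0] / denom[0];
    for (int i = 1; i < n; ++i)
      d[i] = (rhs[i] - low[i] * d[i - 1]) / denom[i];
    V[n - 1] = d[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = d[i] - cp[i] * V[i + 1];

    // divergence guard
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 50.0)
        stop("cable simulation diverged (non-finite or runaway voltage)");
    }
    record(step + 1);
  }

  return List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["times"] = times,
      _["trace"] = trace,
      _["full"] = full);
}

// Count upward crossings of `level` in a trace, restricted to times in
// (t_from, t_to]; linear interpolation is irrelevant for counting.
// [[Rcpp::export(name = ".count_upcrossings")]]
int count_upcrossings(NumericVector times, NumericVector v, double level,
                      double t_from, double t_to) {
  int cnt = 0;
  for (int i = 1; i < v.size(); ++i) {
    if (times[i] <= t_from || times[i] > t_to) continue;
    if (v[i - 1] < level && v[i] >= level) ++cnt;
  }
  return cnt;
}
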