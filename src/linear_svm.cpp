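#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic PRNG for epoch permutations: results must be bitwise
// reproducible across platforms, so we do not touch R's RNG here.
static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13;
  s ^= s >> 17;
  s ^= s << 5;
  return s;
}

// Dual coordinate descent for a soft-margin linear SVM with per-example
// costs:
//
//   min_w 0.5 * ||w||^2 + sum_i C_i * max(0, 1 - y_i * w.x~_i)
//
// where x~_i is x_i augmented with a constant `bias` coordinate (so the
// intercept is regularized like any other weight). The dual is box
// constrained, 0 <= alpha_i <= C_i; each coordinate update is the exact
// one-dimensional minimizer. Examples whose dual variable is pinned at a
// bound with a clearly non-violating gradient are shrunk out of the sweep
// and only revisited for the final convergence check. Sweeps visit the
// active set in a freshly shuffled order each epoch; the solver stops
// when the projected-gradient violation range over the full problem
// drops below `tol`, or after `max_epochs` sweeps.
//
// [[Rcpp::export]]
List dcd_linear_svm(const NumericMatrix &X, const IntegerVector &y,
                    const NumericVector &cost, double bias, int max_epochs,
                    double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n || cost.size() != n)
    stop("y and cost must have one entry per row of X");
  // row-major copy: one contiguous block per example
  std::vector<double> xr((size_t)n * p);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = bias * bias;
    double *row = &xr[(size_t)i * p];
    for (int j = 0; j < p; ++j) {
      const double v = X(i, j);
      row[j] = v;
      s += v * v;
    }
    qii[i] = s;
  }
  std::vector<double> w(p, 0.0), alpha(n, 0.0);
  double wb = 0.0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  uint32_t rng = (uint32_t)seed;
  if (rng == 0u) rng = 88172645u;

  int active = n, epoch = 0;
  double gap = R_PosInf;
  double viol_max_old = R_PosInf, viol_min_old = R_NegInf;
  while (epoch < max_epochs) {
    ++epoch;
    for (int i = active - 1; i > 0; --i) {
      int j = (int)(xorshift32(rng) % (uint32_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double viol_max = R_NegInf, viol_min = R_PosInf;
    for (int t = 0; t < active; ++t) {
      const int i = idx[t];
      const double yi = (double)y[i];
      const double *row = &xr[(size_t)i * p];
      double dec = wb * bias;
      for (int j = 0; j < p; ++j) dec += w[j] * row[j];
      const double G = yi * dec - 1.0;
      const double C = cost[i], a = alpha[i];
      double PG = 0.0;
      if (a <= 0.0) {
        if (G > viol_max_old) {  // pinned at 0, far from violating: shrink
          std::swap(idx[t], idx[--active]);
          --t;
          continue;
        }
        if (G < 0.0) PG = G;
      } else if (a >= C) {
        if (G < viol_min_old) {  // pinned at C, far from violating: shrink
          std::swap(idx[t], idx[--active]);
          --t;
          continue;
        }
        if (G > 0.0) PG = G;
      } else {
        PG = G;
      }
      if (PG > viol_max) viol_max = PG;
      if (PG < viol_min) viol_min = PG;
      if (std::fabs(PG) > 1e-12) {
        double anew = a - G / qii[i];
        if (anew < 0.0) anew = 0.0;
        if (anew > C) anew = C;
        const double d = (anew - a) * yi;
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * row[j];
          wb += d * bias;
          alpha[i] = anew;
        }
      }
    }
    gap = viol_max - viol_min;
    if (gap <= tol) {
      if (active == n) break;
      // converged on the active set: reactivate everything and verify
      active = n;
      viol_max_old = R_PosInf;
      viol_min_old = R_NegInf;
      continue;
    }
    viol_max_old = (viol_max <= 0.0) ? R_PosInf : viol_max;
    viol_min_old = (viol_min >= 0.0) ? R_NegInf : viol_min;
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["intercept"] = wb * bias, _["epochs"] = epoch,
                      _["gap"] = gap, _["converged"] = (gap <= tol));
}
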