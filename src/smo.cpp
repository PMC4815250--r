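#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with RBF kernel,
// maximal-violating-pair working-set selection and a gradient cache
// (Keerthi et al. 2001; Fan et al. 2005).  Solves
//   min_a 1/2 a' Q a - e' a   s.t. 0 <= a_i <= C, y' a = 0,
// with Q_ij = y_i y_j exp(-gamma ||x_i - x_j||^2).
//
// X: n x d, y: +1/-1.  Returns alpha, rho, iterations, and the objective
// gradient (for KKT checks in tests).  Decision values are computed in R.
// [[Rcpp::export]]
List smo_fit_cpp(NumericMatrix X, IntegerVector y, double C, double gamma,
                 double eps = 1e-3, int max_iter = 100000) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive");

  // full RBF kernel matrix (calibration sets are small)
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      const double v = std::exp(-gamma * s);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double inf = std::numeric_limits<double>::infinity();
  int iter = 0;

  while (iter < max_iter) {
    // select maximal violating pair
    double m = -inf, M = inf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) break;
    ++iter;

    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t) {
        G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai +
                        y[j] * K[(size_t)t * n + j] * daj);
      }
    }
  }

  // bias: average y_t G_t over free support vectors, else midpoint of bounds
  double ub = inf, lb = -inf, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum_free += yG;
      ++n_free;
    }
  }
  const double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter,
                      _["grad"] = NumericVector(G.begin(), G.end()));
}
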