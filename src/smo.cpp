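// SVM dual solver: sequential minimal optimisation (SMO) with
// maximal-violating-pair / second-order working-set selection on a
// precomputed kernel matrix (the caller builds it with BLAS, which is much
// faster than per-element kernel evaluation here). Deterministic: no
// randomness, selection ties resolved by lowest index. Intended for the
// moderate training sizes used in this package (n up to a few thousand).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".svm_smo_solve")]]
List svm_smo_solve(NumericMatrix K, NumericVector y, double C,
                   double tol = 1e-3, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label dimension mismatch");

  const double* Kd = REAL(K);
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = grad of 1/2 a'Qa - e'a
  const double tau = 1e-12;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // select i: argmax over I_up of -y_t G_t
    int i = -1;
    double Gmax = -HUGE_VAL, Gmax2 = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up) {
        const double v = -y[t] * G[t];
        if (v > Gmax) { Gmax = v; i = t; }
      }
    }
    // select j: best second-order gain among I_low violators
    int j = -1;
    double obj_min = HUGE_VAL;
    const double* Ki = Kd + (size_t)i * n;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      const double v = y[t] * G[t];
      if (v > Gmax2) Gmax2 = v;
      const double b = Gmax + v;
      if (b > 0) {
        double a = Ki[i] + Kd[(size_t)t * n + t] - 2.0 * y[i] * y[t] * Ki[t];
        if (a <= 0) a = tau;
        const double obj = -(b * b) / a;
        if (obj < obj_min) { obj_min = obj; j = t; }
      }
    }
    if (Gmax + Gmax2 < tol || j == -1) { converged = true; break; }

    const double* Kj = Kd + (size_t)j * n;
    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      // dual quad coef Q_ii + Q_jj + 2Q_ij with Q_ij = y_i y_j K_ij
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = tau;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = tau;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
  }

  // intercept from free support vectors (b such that f = sum a y K + b)
  double bsum = 0.0; int nfree = 0;
  double ub = HUGE_VAL, lb = -HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    const double yg = -y[t] * G[t]; // = y_t - u_t
    const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { bsum += yg; ++nfree; }
    if (up)  ub = std::min(ub, yg);
    if (low) lb = std::max(lb, yg);
  }
  const double b = (nfree > 0) ? bsum / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}
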