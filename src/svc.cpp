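#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Two-class soft-margin linear C-SVC solved in the dual by SMO with
// second-order working-set selection and the classical KKT-violation
// stopping rule.  Training problems here are tiny (tens of vectors), so the
// dense label-scaled Gram matrix Q (Q_ij = y_i y_j <x_i, x_j>) is
// precomputed.
//
// Dual: min 1/2 a'Qa - e'a  s.t. y'a = 0, 0 <= a_i <= C_i.
// Decision f(x) = w.x + b with b = -rho.

// [[Rcpp::export]]
List svc_train_linear_cpp(NumericMatrix X, IntegerVector yR,
                          double cost_pos, double cost_neg,
                          double eps = 1e-3, int max_iter = 200000) {
  const int n = X.nrow();
  const int d = X.ncol();
  if (yR.size() != n) stop("length(y) must equal nrow(X)");

  std::vector<int> y(yR.begin(), yR.end());
  const double *x = REAL(X);  // column-major n x d

  std::vector<double> Q((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      const double *xi = x + i, *xj = x + j;
      for (int k = 0; k < d; ++k) s += xi[(size_t)k * n] * xj[(size_t)k * n];
      s *= y[i] * y[j];
      Q[(size_t)i * n + j] = s;
      Q[(size_t)j * n + i] = s;
    }
  }

  std::vector<double> C(n), alpha(n, 0.0), G(n, -1.0);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? cost_pos : cost_neg;

  const double INF = std::numeric_limits<double>::infinity();
  const double TAU = 1e-12;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // first index: maximal violation in I_up
    double Gmax = -INF, Gmax2 = -INF;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      const double yG = y[t] * G[t];
      const bool up = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (up && -yG > Gmax) { Gmax = -yG; i = t; }
      if (low && yG > Gmax2) Gmax2 = yG;
    }
    if (i < 0 || Gmax + Gmax2 < eps) break;

    // second index: best second-order gain among violating I_low members
    const double *Qi = &Q[(size_t)i * n];
    const double Qii = Qi[i];
    double best = -INF;
    int j = -1;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (!low) continue;
      const double bt = Gmax + y[t] * G[t];
      if (bt <= 0.0) continue;
      // Qi is y-scaled (Qi[t] = y_i y_t K_it), so the curvature along the
      // (i, t) direction is a_t = K_ii + K_tt - 2 K_it:
      double at = Qii + Q[(size_t)t * n + t] -
                  2.0 * (double)(y[i] * y[t]) * Qi[t];
      if (at <= 0.0) at = TAU;
      const double gain = bt * bt / at;
      if (gain > best) { best = gain; j = t; }
    }
    if (j < 0) break;

    const double Qjj = Q[(size_t)j * n + j];
    const double Qij = Qi[j];
    const double Ci = C[i], Cj = C[j];
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Qii + Qjj + 2.0 * Qij;
      if (quad <= 0.0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0.0) {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
      }
      if (diff > Ci - Cj) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; }
      } else {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; }
      }
    } else {
      double quad = Qii + Qjj - 2.0 * Qij;
      if (quad <= 0.0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > Ci) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; }
      } else {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
      }
      if (sum > Cj) {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai != 0.0 || daj != 0.0) {
      const double *Qj = &Q[(size_t)j * n];
      for (int t = 0; t < n; ++t) G[t] += Qi[t] * dai + Qj[t] * daj;
    }
  }

  // rho from free support vectors, else midpoint of the KKT bounds
  double ub = INF, lb = -INF, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  const double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  NumericVector w(d);
  int n_sv = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0.0) {
      ++n_sv;
      const double ay = alpha[t] * y[t];
      for (int k = 0; k < d; ++k) w[k] += ay * x[t + (size_t)k * n];
    }
  }

  return List::create(_["w"] = w, _["b"] = -rho,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["n_sv"] = n_sv, _["iterations"] = iter,
                      _["converged"] = (iter < max_iter));
}
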