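#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// One-vs-rest training for the decoder's inner loop: all K binary C-SVC
// problems of one training set share the same Gram matrix, so it is
// computed once.  The solver is the same SMO as svc_train_linear_cpp.

static void solve_binary(const std::vector<double> &K, const std::vector<int> &y,
                         int n, double cost_pos, double cost_neg, double eps,
                         int max_iter, std::vector<double> &alpha,
                         double &rho) {
  std::vector<double> C(n), G(n, -1.0);
  alpha.assign(n, 0.0);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? cost_pos : cost_neg;

  const double INF = std::numeric_limits<double>::infinity();
  const double TAU = 1e-12;
  for (int iter = 0; iter < max_iter; ++iter) {
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

    const double Kii = K[(size_t)i * n + i];
    double best = -INF;
    int j = -1;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (!low) continue;
      const double bt = Gmax + y[t] * G[t];
      if (bt <= 0.0) continue;
      double at = Kii + K[(size_t)t * n + t] - 2.0 * K[(size_t)i * n + t];
      if (at <= 0.0) at = TAU;
      const double gain = bt * bt / at;
      if (gain > best) { best = gain; j = t; }
    }
    if (j < 0) break;

    const double Kjj = K[(size_t)j * n + j];
    const double Qij = (double)y[i] * y[j] * K[(size_t)i * n + j];
    const double Ci = C[i], Cj = C[j];
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Qij;
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
      double quad = Kii + Kjj - 2.0 * Qij;
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
      const double *Ki = &K[(size_t)i * n];
      const double *Kj = &K[(size_t)j * n];
      const double syi = y[i] * dai, syj = y[j] * daj;
      for (int t = 0; t < n; ++t) {
        G[t] += y[t] * (Ki[t] * syi + Kj[t] * syj);
      }
    }
  }

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
  rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;
}

// [[Rcpp::export]]
List svc_train_ovr_cpp(NumericMatrix X, IntegerVector labels,
                       IntegerVector targets, double cost_pos,
                       double cost_neg, double eps = 1e-3,
                       int max_iter = 200000) {
  const int n = X.nrow();
  const int d = X.ncol();
  const int K_cls = targets.size();
  if (labels.size() != n) stop("length(labels) must equal nrow(X)");

  const double *x = REAL(X);
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      const double *xi = x + i, *xj = x + j;
      for (int k = 0; k < d; ++k) s += xi[(size_t)k * n] * xj[(size_t)k * n];
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  }

  NumericMatrix W(d, K_cls);
  NumericVector b(K_cls);
  std::vector<int> y(n);
  std::vector<double> alpha;
  for (int c = 0; c < K_cls; ++c) {
    bool any_pos = false, any_neg = false;
    for (int t = 0; t < n; ++t) {
      y[t] = (labels[t] == targets[c]) ? 1 : -1;
      if (y[t] > 0) any_pos = true; else any_neg = true;
    }
    if (!any_pos || !any_neg) stop("single-class training set");
    double rho;
    solve_binary(K, y, n, cost_pos, cost_neg, eps, max_iter, alpha, rho);
    for (int t = 0; t < n; ++t) {
      if (alpha[t] > 0.0) {
        const double ay = alpha[t] * y[t];
        for (int k = 0; k < d; ++k) W(k, c) += ay * x[t + (size_t)k * n];
      }
    }
    b[c] = -rho;
  }
  return List::create(_["W"] = W, _["b"] = b);
}
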