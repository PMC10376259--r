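#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Support-vector machine training by sequential minimal optimization with
// maximal-violating-pair working-set selection (Keerthi et al.). Solves
//   min_a 0.5 * sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t. 0 <= a_i <= C, sum_i a_i y_i = 0
// for an RBF kernel K(u, v) = exp(-gamma * ||u - v||^2).

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    const double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double tol = 1e-3, int max_iter = 1000000) {
  const int n = X.nrow();
  // Precompute the kernel matrix; training sets here are at most a few
  // thousand clips, so n^2 doubles are affordable.
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = rbf(X, i, j, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> alpha(n, 0.0);
  // F_i = sum_j alpha_j y_j K_ij - y_i  (decision value minus target,
  // without the offset b)
  std::vector<double> F(n);
  for (int i = 0; i < n; ++i) F[i] = -y[i];

  int iter = 0;
  double b_up = 0, b_low = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: most violating pair
    int i_up = -1, i_low = -1;
    b_up = R_PosInf;
    b_low = R_NegInf;
    for (int t = 0; t < n; ++t) {
      const bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && F[t] < b_up) { b_up = F[t]; i_up = t; }
      if (in_low && F[t] > b_low) { b_low = F[t]; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || b_low - b_up < tol) break;
    const int i = i_up, j = i_low;
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j]
               - 2.0 * K[(size_t)i * n + j];
    if (eta < 1e-12) eta = 1e-12;
    // step t along the feasible pair direction: da_i = y_i*t, da_j = -y_j*t
    double step = (F[j] - F[i]) / eta;
    // box constraints for both multipliers
    double lo, hi;
    if (y[i] > 0) { lo = -alpha[i]; hi = C - alpha[i]; }
    else          { lo = alpha[i] - C; hi = alpha[i]; }
    if (y[j] > 0) { lo = std::max(lo, alpha[j] - C); hi = std::min(hi, alpha[j]); }
    else          { lo = std::max(lo, -alpha[j]);    hi = std::min(hi, C - alpha[j]); }
    if (step > hi) step = hi;
    if (step < lo) step = lo;
    if (std::fabs(step) < 1e-14) break;
    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    for (int t = 0; t < n; ++t)
      F[t] += step * (K[(size_t)i * n + t] - K[(size_t)j * n + t]);
  }

  // offset: average over free support vectors, else midpoint of the bounds
  double b = 0.0;
  int n_free = 0;
  for (int i = 0; i < n; ++i)
    if (alpha[i] > 1e-8 && alpha[i] < C - 1e-8) { b += -F[i]; ++n_free; }
  if (n_free > 0) b /= n_free;
  else b = -(b_up + b_low) / 2.0;

  return List::create(Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
                      Named("b") = b,
                      Named("iterations") = iter);
}

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int m = Xnew.nrow(), n = Xsv.nrow(), p = Xsv.ncol();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = b;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = Xnew(i, k) - Xsv(j, k);
        s += d * d;
      }
      acc += coef[j] * std::exp(-gamma * s);
    }
    out[i] = acc;
  }
  return out;
}
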