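// RBF-kernel C-SVM trained by SMO with maximal-violating-pair working-set
// selection and a duality-gap stopping rule (the libsvm strategy).
// Small-n setting (tens to a few hundred samples): the full kernel matrix is
// precomputed and the gradient is maintained incrementally, so the solver is
// deterministic and reproducible bit-for-bit.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_passes) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = X(i, k) - X(j, k);
        s += d * d;
      }
      const double v = std::exp(-gamma * s);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  // dual: min 1/2 a'Qa - e'a, Q_ij = y_i y_j K_ij, 0 <= a <= C, y'a = 0
  // grad_t = sum_s y_t y_s K_ts a_s - 1
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  const long max_iter = std::max(10000L, 200L * (long)n) * (long)max_passes;
  long iter = 0;
  const double INF = std::numeric_limits<double>::infinity();

  while (iter++ < max_iter) {
    // maximal violating pair: i in I_up maximising -y grad, j in I_low
    // minimising -y grad
    int i = -1, j = -1;
    double gmax = -INF, gmin = INF;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      const double v = -y[t] * grad[t];
      if (up && v > gmax) {
        gmax = v;
        i = t;
      }
      if (low && v < gmin) {
        gmin = v;
        j = t;
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // analytic update of the pair (i, j)
    const double Kii = 1.0, Kjj = 1.0, Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;
    const double ai_old = alpha[i], aj_old = alpha[j];
    // step along the constraint y'a = 0
    // unconstrained optimal step t along alpha_i += y_i t, alpha_j -= y_j t
    double t_step = (gmax - gmin) / eta;
    double ai, aj;
    // clip to the box
    double t_max = INF;
    t_max = std::min(t_max, y[i] > 0 ? C - ai_old : ai_old);
    t_max = std::min(t_max, y[j] > 0 ? aj_old : C - aj_old);
    if (t_step > t_max) t_step = t_max;
    if (t_step <= 0) break;
    ai = ai_old + y[i] * t_step;
    aj = aj_old - y[j] * t_step;
    alpha[i] = ai;
    alpha[j] = aj;
    const double dai = ai - ai_old, daj = aj - aj_old;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * dai * K[(size_t)i * n + t] +
                         y[j] * daj * K[(size_t)j * n + t]);
  }

  // intercept from the KKT conditions: y_t (f_t + b) with f_t = sum a y K
  double b;
  {
    double sum = 0.0, lo = -INF, hi = INF;
    int nfree = 0;
    for (int t = 0; t < n; ++t) {
      const double yg = -y[t] * grad[t];  // equals y_t - f_t at optimum
      const bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && low) {  // free SV
        sum += yg;
        ++nfree;
      } else if (up) {
        lo = std::max(lo, yg);
      } else if (low) {
        hi = std::min(hi, yg);
      }
    }
    if (nfree > 0)
      b = sum / nfree;
    else if (std::isfinite(lo) && std::isfinite(hi))
      b = (lo + hi) / 2.0;
    else
      b = 0.0;
  }

  return List::create(Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
                      Named("b") = b);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] == 0.0) continue;
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = Xtrain(i, k) - Xnew(q, k);
        d2 += d * d;
      }
      s += alpha[i] * y[i] * std::exp(-gamma * d2);
    }
    out[q] = s;
  }
  return out;
}
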