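#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sequential minimal optimization for the epsilon-SVR dual over a
// precomputed kernel matrix K (n x n):
//
//   min over a in R^{2n}:  1/2 b(a)' K b(a) + eps * sum(a) - y' b(a)
//   with b(a)_i = a_i - a_{n+i},  0 <= a <= C,  sum_{i<=n} a_i = sum_{i>n} a_i
//
// Working-set selection is second order (libsvm WSS2): the first index
// maximises the KKT violation, the second maximises the guaranteed
// objective decrease. The pair curvature H = K_ii + K_jj - 2 K_ij is
// sign-free. Deterministic; no randomness anywhere.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double eps,
               double tol, int max_iter) {
  const int n = K.nrow();
  const int N = 2 * n;
  std::vector<double> a(N, 0.0), g(N), s(N), kdiag(n);
  for (int i = 0; i < n; ++i) kdiag[i] = K(i, i);
  for (int t = 0; t < N; ++t) {
    s[t] = (t < n) ? 1.0 : -1.0;
    // gradient at a = 0: g_i = eps - y_i (alpha side), eps + y_i (alpha* side)
    g[t] = eps - s[t] * y[t % n];
  }
  const double TAU = 1e-12;

  int iter = 0;
  while (iter < max_iter) {
    // first index: maximal violation over I_up
    int i = -1;
    double up_best = -INFINITY;
    for (int t = 0; t < N; ++t) {
      bool in_up = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
      if (!in_up) continue;
      double v = -s[t] * g[t];
      if (v > up_best) { up_best = v; i = t; }
    }
    if (i < 0) break;
    const int ib = i % n;

    // second index: max objective decrease among sufficiently lower I_low
    int j = -1;
    double low_min = INFINITY, dec_best = -INFINITY;
    for (int t = 0; t < N; ++t) {
      bool in_low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (!in_low) continue;
      double v = -s[t] * g[t];
      if (v < low_min) low_min = v;
      double diff = up_best - v;
      if (diff > 0) {
        double H = kdiag[ib] + kdiag[t % n] - 2.0 * K(ib, t % n);
        if (H < TAU) H = TAU;
        double dec = diff * diff / H;
        if (dec > dec_best) { dec_best = dec; j = t; }
      }
    }
    if (j < 0 || up_best - low_min <= tol) break;
    const int jb = j % n;

    double H = kdiag[ib] + kdiag[jb] - 2.0 * K(ib, jb);
    if (H < TAU) H = TAU;
    double vj = -s[j] * g[j];
    double d = (up_best - vj) / H;
    // box caps: a_i moves by +s_i d, a_j by -s_j d (keeps sum s'a = 0)
    double cap_i = (s[i] > 0) ? (C - a[i]) : a[i];
    double cap_j = (s[j] > 0) ? a[j] : (C - a[j]);
    if (d > cap_i) d = cap_i;
    if (d > cap_j) d = cap_j;
    if (d <= 0) break;

    a[i] += s[i] * d;
    a[j] -= s[j] * d;
    ++iter;
    for (int t = 0; t < N; ++t) {
      g[t] += s[t] * d * (K(t % n, ib) - K(t % n, jb));
    }
  }

  NumericVector beta(n);
  for (int i2 = 0; i2 < n; ++i2) beta[i2] = a[i2] - a[n + i2];

  // objective: 1/2 beta'K beta + eps*sum(a) - y'beta
  double quad = 0.0, lin = 0.0, asum = 0.0;
  std::vector<double> f(n, 0.0);
  for (int i2 = 0; i2 < n; ++i2) {
    for (int j2 = 0; j2 < n; ++j2) f[i2] += K(i2, j2) * beta[j2];
    quad += beta[i2] * f[i2];
    lin += y[i2] * beta[i2];
  }
  for (int t = 0; t < N; ++t) asum += a[t];
  double objective = 0.5 * quad + eps * asum - lin;

  // bias from free support vectors' KKT equalities, midpoint fallback
  double bsum = 0.0; int bcnt = 0;
  for (int i2 = 0; i2 < n; ++i2) {
    if (a[i2] > 1e-10 * C && a[i2] < C * (1 - 1e-10)) {
      bsum += y[i2] - eps - f[i2]; ++bcnt;
    }
    if (a[n + i2] > 1e-10 * C && a[n + i2] < C * (1 - 1e-10)) {
      bsum += y[i2] + eps - f[i2]; ++bcnt;
    }
  }
  double b;
  if (bcnt > 0) {
    b = bsum / bcnt;
  } else {
    double up_best = -INFINITY, low_best = INFINITY;
    for (int t = 0; t < N; ++t) {
      double v = -s[t] * g[t];
      bool in_up  = (s[t] > 0) ? (a[t] < C) : (a[t] > 0);
      bool in_low = (s[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (in_up && v > up_best) up_best = v;
      if (in_low && v < low_best) low_best = v;
    }
    b = 0.5 * (up_best + low_best);
    if (!std::isfinite(b)) b = 0.0;
  }

  NumericVector alpha(n), alpha_star(n);
  for (int i2 = 0; i2 < n; ++i2) { alpha[i2] = a[i2]; alpha_star[i2] = a[n + i2]; }

  return List::create(_["beta"] = beta, _["b"] = b,
                      _["alpha"] = alpha, _["alpha_star"] = alpha_star,
                      _["objective"] = objective, _["iterations"] = iter);
}
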