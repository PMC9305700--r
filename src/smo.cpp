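#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft-margin SVM dual solver (sequential minimal optimization with
// maximal-violating-pair working-set selection):
//   min 0.5 a' Q a - e' a,  Q_ij = y_i y_j K_ij,  0 <= a <= C,  y' a = 0.
// K is the (precomputed, PSD) kernel Gram matrix.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double m_val = 0, M_val = 0;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    m_val = -HUGE_VAL;
    M_val = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m_val) { m_val = v; i = t; }
      if (low && v < M_val) { M_val = v; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < tol) break;

    double h = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (h < 1e-12) h = 1e-12;
    double step = (m_val - M_val) / h; // > 0
    // direction d_i = y_i, d_j = -y_j keeps y'a constant
    double tmin = -HUGE_VAL, tmax = HUGE_VAL;
    if (y[i] > 0) { tmax = std::min(tmax, C - alpha[i]); tmin = std::max(tmin, -alpha[i]); }
    else          { tmax = std::min(tmax, alpha[i]);     tmin = std::max(tmin, alpha[i] - C); }
    if (y[j] > 0) { tmax = std::min(tmax, alpha[j]);     tmin = std::max(tmin, alpha[j] - C); }
    else          { tmax = std::min(tmax, C - alpha[j]); tmin = std::max(tmin, -alpha[j]); }
    if (step > tmax) step = tmax;
    if (step < tmin) step = tmin;
    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    // numeric cleanup at the box
    if (alpha[i] < 1e-14) alpha[i] = 0; else if (alpha[i] > C - 1e-14 * C) alpha[i] = C;
    if (alpha[j] < 1e-14) alpha[j] = 0; else if (alpha[j] > C - 1e-14 * C) alpha[j] = C;
    for (int t = 0; t < n; ++t)
      G[t] += step * y[t] * (K(t, i) - K(t, j));
  }

  // bias from free support vectors, else midpoint of the violating bounds
  double bsum = 0;
  int bcnt = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-10 && alpha[t] < C * (1 - 1e-10)) {
      bsum += -y[t] * G[t];
      bcnt++;
    }
  double b = bcnt > 0 ? bsum / bcnt : 0.5 * (m_val + M_val);

  // dual objective in maximization form: sum(a) - 0.5 a'Qa
  // using G = Qa - e:  a'Qa = a'(G + e) = a'G + sum(a)
  double sum_a = 0, aG = 0;
  for (int t = 0; t < n; ++t) { sum_a += alpha[t]; aG += alpha[t] * G[t]; }
  double obj = sum_a - 0.5 * (aG + sum_a);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["objective"] = obj,
                      _["converged"] = iter < max_iter);
}
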