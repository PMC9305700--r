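#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(na, nb) - 1).  a[0] must be 1 (coefficients are normalized in R).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < (int)zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  int n = x.size();
  NumericVector y(n);
  if (nf == 1) {
    for (int t = 0; t < n; ++t) y[t] = bb[0] * x[t];
    return y;
  }
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[nf - 2] = bb[nf - 1] * xt - aa[nf - 1] * yt;
    y[t] = yt;
  }
  return y;
}
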