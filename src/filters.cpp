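#include <Rcpp.h>
using namespace Rcpp;

// IIR filter, direct form II transposed, with initial filter state zi
// (length max(length(a), length(b)) - 1). a[0] must be 1.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 0; i < nfilt - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[nfilt - 2] = bb[nfilt - 1] * xm - aa[nfilt - 1] * ym;
    y[m] = ym;
  }
  return y;
}
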