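#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state.
// a[0] is assumed to be 1 (the R wrapper normalises).
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt - 1, 0.0);
  for (int i = 0; i < (int)zi.size() && i < nfilt - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nfilt - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nfilt - 2] = bb[nfilt - 1] * xi - aa[nfilt - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Bernoulli thinning of a per-millisecond rate with an absolute refractory
// period; u are pre-drawn uniforms (one per sample) so the draw order is
// fixed by the caller's RNG stream.
// [[Rcpp::export]]
IntegerVector thin_spikes(NumericVector p, NumericVector u, int refractory_ms) {
  int n = p.size();
  std::vector<int> out;
  int last = -refractory_ms - 1;
  for (int i = 0; i < n; ++i) {
    if (i - last <= refractory_ms) continue;
    if (u[i] < p[i]) { out.push_back(i); last = i; }
  }
  return wrap(out);
}
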