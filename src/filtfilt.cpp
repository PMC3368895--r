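// Zero-phase IIR filtering of matrix rows: odd-reflection padding, forward
// pass, backward pass, crop. Coefficients come from signal::butter on the
// R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// direct-form II transposed; initial state = zi * x[0] (steady-state
// initial conditions, so a constant input yields a constant output)
static void iir_filter(const std::vector<double> &b, const std::vector<double> &a,
                       const std::vector<double> &zi, std::vector<double> &x) {
  const int n = (int)x.size();
  const int nb = (int)b.size(), na = (int)a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int k = 0; k < nz && k < (int)zi.size(); ++k) z[k] = zi[k] * x[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = (nz > 0 ? z[0] : 0.0) + b[0] * xi;
    for (int k = 0; k < nz - 1; ++k)
      z[k] = z[k + 1] + xi * (k + 1 < nb ? b[k + 1] : 0.0)
                      - yi * (k + 1 < na ? a[k + 1] : 0.0);
    if (nz > 0)
      z[nz - 1] = xi * (nz < nb ? b[nz] : 0.0) - yi * (nz < na ? a[nz] : 0.0);
    x[i] = yi;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericVector b, NumericVector a,
                                NumericVector zi, NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  const int nf = std::max(b.size(), a.size());
  const int pl = std::min(3 * nf, nc - 1);
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  std::vector<double> zz(zi.begin(), zi.end());
  // normalize by a[0]
  for (size_t i = 0; i < bb.size(); ++i) bb[i] /= aa[0];
  for (size_t i = 0; i < aa.size(); ++i) aa[i] /= aa[0];
  NumericMatrix out(nr, nc);
  std::vector<double> w;
  for (int r = 0; r < nr; ++r) {
    w.assign(nc + 2 * pl, 0.0);
    // odd reflection about the end points
    for (int i = 0; i < pl; ++i)
      w[i] = 2.0 * X(r, 0) - X(r, pl - i);
    for (int i = 0; i < nc; ++i) w[pl + i] = X(r, i);
    for (int i = 0; i < pl; ++i)
      w[pl + nc + i] = 2.0 * X(r, nc - 1) - X(r, nc - 2 - i);
    iir_filter(bb, aa, zz, w);
    std::reverse(w.begin(), w.end());
    iir_filter(bb, aa, zz, w);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < nc; ++i) out(r, i) = w[pl + i];
  }
  return out;
}
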