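#include <Rcpp.h>
using namespace Rcpp;

// IIR filtering (direct-form II transposed) applied independently to each
// column of X. Coefficients follow the usual b/a convention with a[0]
// normalized to 1 by the caller-facing wrapper. A plain loop keeps the
// recursion in C++; zero-phase behaviour (forward-backward application and
// odd-symmetric edge extension) is handled on the R side.
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(NumericVector b, NumericVector a, NumericMatrix X) {
  const int n = X.nrow();
  const int m = X.ncol();
  const int nb = b.size();
  const int na = a.size();
  const int nz = std::max(na, nb) - 1;

  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;

  NumericMatrix Y(n, m);
  std::vector<double> z(nz);

  for (int j = 0; j < m; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    const double* x = &X(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = bb[0] * xi + z[0];
      for (int k = 0; k < nz - 1; ++k)
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      if (nz > 0)
        z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
      y[i] = yi;
    }
  }
  return Y;
}
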