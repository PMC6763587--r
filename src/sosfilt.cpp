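#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad (second-order-section) filtering of each column of x,
// direct form II transposed, zero initial conditions. sos has one row per
// section: b0 b1 b2 1 a1 a2.
// [[Rcpp::export]]
NumericMatrix sos_filt_cpp(NumericMatrix x, NumericMatrix sos) {
  const int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  NumericMatrix y(clone(x));
  double *py = &y[0];
  for (int c = 0; c < nc; ++c) {
    double *col = py + (size_t)c * n;
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = col[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        col[i] = yi;
      }
    }
  }
  return y;
}

// Forward-backward (zero-phase) cascaded biquad filtering of each column,
// zero initial conditions on both passes; the caller handles edge padding.
// [[Rcpp::export]]
NumericMatrix sos_filtfilt_cpp(NumericMatrix x, NumericMatrix sos) {
  const int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  NumericMatrix y(clone(x));
  double *py = &y[0];
  for (int c = 0; c < nc; ++c) {
    double *col = py + (size_t)c * n;
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = col[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        col[i] = yi;
      }
    }
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int i = n - 1; i >= 0; --i) {
        const double xi = col[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        col[i] = yi;
      }
    }
  }
  return y;
}
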