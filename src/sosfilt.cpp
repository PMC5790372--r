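#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads in direct form II transposed.
// sos: k x 6 matrix, rows (b0, b1, b2, 1, a1, a2); zi: k x 2 initial states.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    double *p = REAL(y);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xn = p[i];
      const double yn = b0 * xn + z1;
      z1 = b1 * xn - a1 * yn + z2;
      z2 = b2 * xn - a2 * yn;
      p[i] = yn;
    }
  }
  return y;
}
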