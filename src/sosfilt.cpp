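#include <Rcpp.h>
using namespace Rcpp;

// Second-order-section IIR filtering, direct form II transposed, with
// explicit state so that block-wise (streaming) application is bit-identical
// to whole-record application.
//
// sos: L x 6 matrix, rows (b0, b1, b2, 1, a1, a2)
// x:   input vector
// zi:  L x 2 state matrix (zeros for rest state)
// Returns list(y, zf).
// [[Rcpp::export]]
List sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int L = sos.nrow(), n = x.size();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  if (zi.nrow() != L || zi.ncol() != 2) stop("zi must be L x 2");
  NumericVector y(n);
  NumericMatrix z = clone(zi);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < L; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double out = b0 * v + z(s, 0);
      z(s, 0) = b1 * v - a1 * out + z(s, 1);
      z(s, 1) = b2 * v - a2 * out;
      v = out;
    }
    y[i] = v;
  }
  return List::create(_["y"] = y, _["zf"] = z);
}

// Channel-wise SOS filtering of a channels x samples matrix with per-channel
// state (L x 2 x nch array flattened to L*2 x nch matrix).
// [[Rcpp::export]]
List sosfilt_mat_cpp(NumericMatrix sos, NumericMatrix x, NumericMatrix zi) {
  const int L = sos.nrow(), nch = x.nrow(), n = x.ncol();
  if (zi.nrow() != 2 * L || zi.ncol() != nch) stop("zi must be (2L) x nch");
  NumericMatrix y(nch, n);
  NumericMatrix z = clone(zi);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < n; ++i) {
      double v = x(c, i);
      for (int s = 0; s < L; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        const double out = b0 * v + z(2 * s, c);
        z(2 * s, c) = b1 * v - a1 * out + z(2 * s + 1, c);
        z(2 * s + 1, c) = b2 * v - a2 * out;
        v = out;
      }
      y(c, i) = v;
    }
  }
  return List::create(_["y"] = y, _["zf"] = z);
}
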