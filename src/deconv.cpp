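#include <Rcpp.h>
using namespace Rcpp;

// Side-to-side deconvolution recursion ("excavator" walk).
//
// Walking the amplitude vector x with an arm of d points (fractional, read by
// linear interpolation of the already-computed output):
//
//   out[i] = x[i] - sum_{m=1}^{k} rho[m-1] * out[i - m*d]
//
// with out = x wherever i - m*d falls before the start.  k = 2S subtraction
// terms for a coupling partner of spin S (k = 1 for the usual spin-1/2 case);
// rho[m-1] = 1 for theta = 0, and rho = (far line)/(near line) amplitude ratio
// along the walk for the tilted doublet.  d must be >= 1 so that interpolated
// reads only touch indices < i.
// [[Rcpp::export]]
NumericVector cpp_side_deconv(NumericVector x, double d, NumericVector rho) {
  const int n = x.size();
  const int k = rho.size();
  if (d < 1.0) stop("arm length below one grid step");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int m = 1; m <= k; ++m) {
      double pos = i - m * d;
      if (pos < 0.0) continue;
      int j = (int)std::floor(pos);
      double f = pos - j;
      double ov;
      if (f > 0.0 && j + 1 < n)
        ov = (1.0 - f) * out[j] + f * out[j + 1];
      else
        ov = out[j];
      v -= rho[m - 1] * ov;
    }
    out[i] = v;
  }
  return out;
}

// y[i] = x[i + s] with linear interpolation, zero outside the support.
// [[Rcpp::export]]
NumericVector cpp_shift_interp(NumericVector x, double s) {
  const int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double pos = i + s;
    if (pos < 0.0 || pos > n - 1.0) { y[i] = 0.0; continue; }
    int j = (int)std::floor(pos);
    double f = pos - j;
    y[i] = (f > 0.0 && j + 1 < n) ? (1.0 - f) * x[j] + f * x[j + 1] : x[j];
  }
  return y;
}
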