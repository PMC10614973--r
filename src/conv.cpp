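#include <Rcpp.h>
using namespace Rcpp;

// Same-length discrete convolution of x with a centered, odd-length,
// symmetric kernel w (w[h] is the center tap), zero padding outside x.
// Accumulation in long double: the band-limited responses probed here decay
// like exp(-2*pi^2*sigma^2*f^2) and reach ~1e-14 of the kernel mass near the
// top of the analyzed band, where plain double accumulation would lose the
// result to cancellation. Symmetry halves the multiplies:
// y[i] = w[h]*x[i] + sum_k w[h+k]*(x[i-k] + x[i+k]).
// [[Rcpp::export(name = ".conv_same_sym")]]
NumericVector conv_same_sym(NumericVector x, NumericVector w) {
  const int n = x.size();
  const int m = w.size();
  if (m % 2 == 0) stop("kernel length must be odd");
  const int h = (m - 1) / 2;
  for (int k = 0; k < h; ++k) {
    if (w[k] != w[m - 1 - k]) stop("kernel must be symmetric about its center");
  }
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* wc = wp + h;  // center tap
  NumericVector out(n);
  const int lo = (h < n) ? h : n;            // first index with full left support
  const int hi = (n - h > lo) ? n - h : lo;  // one past last with full right support
  for (int i = 0; i < lo; ++i) {             // left edge: bounds-checked
    long double acc = (long double)wc[0] * xp[i];
    for (int k = 1; k <= h; ++k) {
      long double s = 0.0L;
      if (i - k >= 0) s += xp[i - k];
      if (i + k < n)  s += xp[i + k];
      acc += (long double)wc[k] * s;
    }
    out[i] = (double)acc;
  }
  for (int i = lo; i < hi; ++i) {            // interior: branch-free
    long double acc = (long double)wc[0] * xp[i];
    const double* xl = xp + i;
    for (int k = 1; k <= h; ++k) {
      acc += (long double)wc[k] * (xl[-k] + xl[k]);
    }
    out[i] = (double)acc;
  }
  for (int i = hi; i < n; ++i) {             // right edge: bounds-checked
    long double acc = (long double)wc[0] * xp[i];
    for (int k = 1; k <= h; ++k) {
      long double s = 0.0L;
      if (i - k >= 0) s += xp[i - k];
      if (i + k < n)  s += xp[i + k];
      acc += (long double)wc[k] * s;
    }
    out[i] = (double)acc;
  }
  return out;
}
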