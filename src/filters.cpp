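#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients as from signal::butter:
// a[0] is assumed normalized to 1. Zero initial conditions.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 != 1.0) {
    for (int i = 0; i <= nz; ++i) { bb[i] /= a0; aa[i] /= a0; }
  }
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}

// Cascade of biquad sections applied in one pass (direct form II transposed).
// b, a: 3 x nsec matrices of numerator/denominator coefficients, a(0,s) = 1.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericMatrix b, NumericMatrix a, NumericVector x) {
  int n = x.size(), nsec = b.ncol();
  NumericVector y = clone(x);
  double* v = REAL(y);
  for (int s = 0; s < nsec; ++s) {
    const double b0 = b(0, s), b1 = b(1, s), b2 = b(2, s);
    const double a1 = a(1, s), a2 = a(2, s);
    double z1 = 0.0, z2 = 0.0;
    for (int t = 0; t < n; ++t) {
      const double xt = v[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      v[t] = yt;
    }
  }
  return y;
}

// Piecewise-constant per-epoch gains applied to a signal with a linear
// crossfade of `fade` samples centred on each epoch boundary.
// gains has one entry per epoch of `epoch_len` samples; signal length may
// exceed n_epochs * epoch_len only by < epoch_len (tail uses last gain).
// [[Rcpp::export]]
NumericVector apply_epoch_gains(NumericVector x, NumericVector gains,
                                int epoch_len, int fade) {
  int n = x.size(), ne = gains.size();
  NumericVector y(n);
  const double* xv = REAL(x);
  double* yv = REAL(y);
  int half = fade / 2;
  for (int e = 0; e < ne; ++e) {
    int lo = e * epoch_len;
    int hi = std::min(lo + epoch_len, n);
    if (lo >= n) break;
    const double g = gains[e];
    int a = lo, b = hi;
    if (fade > 0) {
      // leading half-fade: ramp from previous epoch's gain
      if (e > 0) {
        int stop = std::min(lo + half, hi);
        const double g0 = gains[e - 1];
        for (int t = lo; t < stop; ++t) {
          double frac = 0.5 + (double)(t - lo + 1) / fade;  // (0.5, 1]
          yv[t] = xv[t] * (g0 + (g - g0) * frac);
        }
        a = stop;
      }
      // trailing half-fade: ramp towards next epoch's gain
      if (e < ne - 1 && hi == lo + epoch_len) {
        int start = std::max(hi - half, a);
        const double g1 = gains[e + 1];
        for (int t = start; t < hi; ++t) {
          double frac = (double)(t - (hi - half) + 1) / fade;  // (0, 0.5]
          yv[t] = xv[t] * (g + (g1 - g) * frac);
        }
        b = start;
      }
    }
    for (int t = a; t < b; ++t) yv[t] = xv[t] * g;
  }
  // tail beyond the last epoch keeps the last gain
  for (int t = ne * epoch_len; t < n; ++t) yv[t] = xv[t] * gains[ne - 1];
  return y;
}
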