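#include <Rcpp.h>
using namespace Rcpp;

// Per-chunk sum, sum of squares, min and max of a signal, for the
// still-window and non-wear window statistics. One pass, no copies.
// [[Rcpp::export]]
NumericMatrix chunk_stats_cpp(NumericVector x, int chunk) {
  int n = x.size();
  int nc = n / chunk;
  NumericMatrix out(nc, 4);
  for (int c = 0; c < nc; ++c) {
    double s = 0.0, s2 = 0.0;
    double mn = x[(R_xlen_t)c * chunk], mx = mn;
    R_xlen_t base = (R_xlen_t)c * chunk;
    for (int i = 0; i < chunk; ++i) {
      double v = x[base + i];
      s += v; s2 += v * v;
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    out(c, 0) = s; out(c, 1) = s2; out(c, 2) = mn; out(c, 3) = mx;
  }
  return out;
}
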