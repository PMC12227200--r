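#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Type-7 (linear interpolation between order statistics) quantile of the
// window x[k-before .. k+after], clipped to [0, n), for every frame k.
// O(n * w) via nth_element; fast enough for hour-long recordings
// (~5e3 frames, w ~ 200-400) at cohort scale.
static NumericVector roll_quantile_impl(const NumericVector& x, int before,
                                        int after, double prob) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (prob < 0.0 || prob > 1.0) stop("prob must be in [0, 1]");
  if (before < 0 || after < 0) stop("window offsets must be >= 0");

  std::vector<double> buf;
  buf.reserve(before + after + 1);

  for (int k = 0; k < n; ++k) {
    int lo = std::max(0, k - before);
    int hi = std::min(n - 1, k + after);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);

    double h = (m - 1) * prob;
    int j = (int)std::floor(h);
    double g = h - j;
    std::nth_element(buf.begin(), buf.begin() + j, buf.end());
    double q = buf[j];
    if (g > 0.0 && j + 1 < m) {
      std::nth_element(buf.begin() + j + 1, buf.begin() + j + 1, buf.end());
      q += g * (buf[j + 1] - q);
    }
    out[k] = q;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector roll_quantile_cpp(NumericVector x, int half, double prob) {
  return roll_quantile_impl(x, half, half, prob);
}

// [[Rcpp::export]]
NumericVector roll_quantile_trailing_cpp(NumericVector x, int before,
                                         double prob) {
  return roll_quantile_impl(x, before, 0, prob);
}
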