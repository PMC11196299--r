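#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding nearest-rank percentile over centered windows.
//
// For each center index (1-based), collects the valid samples inside the
// window [center - halfwin, center + halfwin] clipped to the signal, and
// returns the nearest-rank percentile: with m valid samples sorted ascending,
// the value at rank ceil(p * m). frac_valid is m over the nominal window
// length (2*halfwin + 1), so samples lost to clipping or masking both reduce
// it; callers use it to invalidate grid points with insufficient support.
//
// [[Rcpp::export(name = ".windowed_percentile")]]
List windowed_percentile(NumericVector x, LogicalVector valid,
                         IntegerVector centers, int halfwin, double p) {
  const int n = x.size();
  const int m = centers.size();
  if (valid.size() != n) stop("x and valid must have equal length");
  if (halfwin < 0) stop("halfwin must be non-negative");
  if (p <= 0.0 || p >= 1.0) stop("p must be in (0, 1)");
  const int wlen = 2 * halfwin + 1;
  NumericVector out(m);
  NumericVector frac(m);
  std::vector<double> buf;
  buf.reserve(wlen);
  for (int j = 0; j < m; ++j) {
    const int c = centers[j] - 1;
    if (c < 0 || c >= n) stop("center index out of range");
    const int lo = std::max(0, c - halfwin);
    const int hi = std::min(n - 1, c + halfwin);
    buf.clear();
    for (int i = lo; i <= hi; ++i) {
      if (valid[i]) buf.push_back(x[i]);
    }
    const int k = (int)buf.size();
    frac[j] = (double)k / (double)wlen;
    if (k == 0) {
      out[j] = NA_REAL;
      continue;
    }
    int r = (int)std::ceil(p * (double)k);
    if (r < 1) r = 1;
    if (r > k) r = k;
    std::nth_element(buf.begin(), buf.begin() + (r - 1), buf.end());
    out[j] = buf[r - 1];
  }
  return List::create(_["value"] = out, _["frac_valid"] = frac);
}
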