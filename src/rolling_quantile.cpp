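#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling quantile over a centered window of +/- halfwin samples, truncated
// (not padded) at the trace edges. Quantile by linear interpolation between
// order statistics (R type 7). Maintains a sorted window with binary-search
// insert/erase: O(T * W) worst case with a small constant.
// [[Rcpp::export]]
NumericVector roll_quantile_cpp(NumericVector x, int halfwin, double p) {
  const int n = x.size();
  if (halfwin < 0) stop("halfwin must be >= 0");
  if (p < 0.0 || p > 1.0) stop("p must be in [0, 1]");
  NumericVector out(n);
  std::vector<double> win;
  win.reserve(2 * halfwin + 2);
  int hi0 = std::min(halfwin, n - 1);
  for (int j = 0; j <= hi0; ++j) win.push_back(x[j]);
  std::sort(win.begin(), win.end());
  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      int add = t + halfwin;
      if (add < n) {
        win.insert(std::lower_bound(win.begin(), win.end(), x[add]), x[add]);
      }
      int drop = t - halfwin - 1;
      if (drop >= 0) {
        win.erase(std::lower_bound(win.begin(), win.end(), x[drop]));
      }
    }
    const int m = win.size();
    double h = (m - 1) * p;
    int j = (int)std::floor(h);
    double g = h - j;
    out[t] = (j + 1 < m) ? win[j] + g * (win[j + 1] - win[j]) : win[j];
  }
  return out;
}
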