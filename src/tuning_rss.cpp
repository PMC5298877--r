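#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Residual sum of squares of the constrained double-Gaussian tuning model at
// fixed (theta_p, sigma), with offset and the two lobe amplitudes profiled
// out by solving the 3x3 normal equations (tiny ridge guards the
// near-collinear large-sigma limit). Used as the optimizer objective; the
// reported coefficients are recomputed in R at the optimum.
// [[Rcpp::export]]
double tuning_rss_cpp(double theta_p, double sigma, NumericVector directions,
                      NumericVector y) {
  const int n = y.size();
  const double inv2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> b1(n), b2(n);
  for (int i = 0; i < n; ++i) {
    double a1 = std::fabs(directions[i] - theta_p);
    double d1 = a1 - 360.0 * std::floor(a1 / 360.0);
    if (d1 > 180.0) d1 = 360.0 - d1;
    double a2 = std::fabs(directions[i] - theta_p - 180.0);
    double d2 = a2 - 360.0 * std::floor(a2 / 360.0);
    if (d2 > 180.0) d2 = 360.0 - d2;
    b1[i] = std::exp(-d1 * d1 * inv2);
    b2[i] = std::exp(-d2 * d2 * inv2);
  }
  // normal equations for X = [1, b1, b2]
  double s1 = n, sb1 = 0, sb2 = 0, s11 = 0, s12 = 0, s22 = 0;
  double sy = 0, sy1 = 0, sy2 = 0;
  for (int i = 0; i < n; ++i) {
    sb1 += b1[i]; sb2 += b2[i];
    s11 += b1[i] * b1[i]; s12 += b1[i] * b2[i]; s22 += b2[i] * b2[i];
    sy += y[i]; sy1 += b1[i] * y[i]; sy2 += b2[i] * y[i];
  }
  const double ridge = 1e-10 * (1.0 + s11 + s22);
  double A[3][3] = {{s1 + ridge, sb1, sb2},
                    {sb1, s11 + ridge, s12},
                    {sb2, s12, s22 + ridge}};
  double rhs[3] = {sy, sy1, sy2};
  // Gaussian elimination with partial pivoting
  for (int k = 0; k < 3; ++k) {
    int p = k;
    for (int r = k + 1; r < 3; ++r)
      if (std::fabs(A[r][k]) > std::fabs(A[p][k])) p = r;
    if (p != k) {
      for (int c = 0; c < 3; ++c) std::swap(A[k][c], A[p][c]);
      std::swap(rhs[k], rhs[p]);
    }
    for (int r = k + 1; r < 3; ++r) {
      double f = A[r][k] / A[k][k];
      for (int c = k; c < 3; ++c) A[r][c] -= f * A[k][c];
      rhs[r] -= f * rhs[k];
    }
  }
  double co[3];
  for (int k = 2; k >= 0; --k) {
    double v = rhs[k];
    for (int c = k + 1; c < 3; ++c) v -= A[k][c] * co[c];
    co[k] = v / A[k][k];
  }
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - co[0] - co[1] * b1[i] - co[2] * b2[i];
    rss += r * r;
  }
  return rss;
}
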