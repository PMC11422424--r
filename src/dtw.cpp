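#include <Rcpp.h>
using namespace Rcpp;

// Banded DTW with the classic symmetric step pattern: diagonal steps cost
// twice the local distance, horizontal/vertical steps cost it once, and the
// first cell is charged 2*d(1,1). Cells outside the Sakoe-Chiba band
// |i - j| <= w are inadmissible. Local cost is |x_i - y_j|. Returns the
// unnormalized cumulative cost at (n, m), or -1 when no admissible path
// reaches the endpoint.

// [[Rcpp::export]]
double dtw_band_cpp(NumericVector x, NumericVector y, int w) {
  const int n = x.size(), m = y.size();
  const double inf = R_PosInf;
  NumericMatrix g(n, m);
  std::fill(g.begin(), g.end(), inf);
  for (int i = 0; i < n; ++i) {
    int jlo = std::max(0, i - w), jhi = std::min(m - 1, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::fabs(x[i] - y[j]);
      if (i == 0 && j == 0) {
        g(0, 0) = 2.0 * d;
        continue;
      }
      double best = inf;
      if (i > 0 && j > 0 && g(i - 1, j - 1) < inf)
        best = g(i - 1, j - 1) + 2.0 * d;
      if (i > 0 && g(i - 1, j) < inf)
        best = std::min(best, g(i - 1, j) + d);
      if (j > 0 && g(i, j - 1) < inf)
        best = std::min(best, g(i, j - 1) + d);
      g(i, j) = best;
    }
  }
  double res = g(n - 1, m - 1);
  return (res == inf) ? -1.0 : res;
}

// [[Rcpp::export]]
NumericMatrix pairwise_dtw_cpp(NumericMatrix traj, int w) {
  const int n = traj.nrow();
  NumericMatrix D(n, n);
  for (int a = 0; a < n; ++a) {
    NumericVector xa = traj(a, _);
    for (int b = a + 1; b < n; ++b) {
      double d = dtw_band_cpp(xa, traj(b, _), w);
      D(a, b) = d;
      D(b, a) = d;
    }
  }
  return D;
}
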