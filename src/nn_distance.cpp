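// Mean nearest-neighbor distance among lattice points, via expanding
// Chebyshev ring search on an occupancy grid (exact Euclidean nearest).
#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_mean_nn_distance(IntegerVector row, IntegerVector col,
                            int width, int height) {
  int n = row.size();
  if (n < 2) stop("need at least 2 points");
  std::vector<char> occ((size_t)width * height, 0);
  for (int i = 0; i < n; ++i) {
    if (row[i] < 0 || row[i] >= height || col[i] < 0 || col[i] >= width)
      stop("point (%d,%d) outside %dx%d grid", row[i], col[i], height, width);
    occ[(size_t)row[i] * width + col[i]] = 1;
  }
  double total = 0.0;
  int dmax = std::max(width, height);
  for (int i = 0; i < n; ++i) {
    int r0 = row[i], c0 = col[i];
    long long best = LLONG_MAX;
    for (int d = 1; d <= dmax; ++d) {
      if ((long long)d * d > best) break;
      int rlo = r0 - d, rhi = r0 + d, clo = c0 - d, chi = c0 + d;
      for (int rr = rlo; rr <= rhi; ++rr) {
        if (rr < 0 || rr >= height) continue;
        bool edgeRow = (rr == rlo || rr == rhi);
        int cstep = edgeRow ? 1 : (chi - clo);
        for (int cc = clo; cc <= chi; cc += cstep) {
          if (cc < 0 || cc >= width) continue;
          if (occ[(size_t)rr * width + cc]) {
            long long dd = (long long)(rr - r0) * (rr - r0) +
                           (long long)(cc - c0) * (cc - c0);
            if (dd > 0 && dd < best) best = dd;
          }
        }
      }
    }
    if (best == LLONG_MAX)
      stop("duplicate-only point set: no distinct nearest neighbor");
    total += std::sqrt((double)best);
  }
  return total / n;
}
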