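#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Edge list of the limited penetrable horizontal visibility graph (1-based,
// i < j, lexicographically sorted).  An edge (i, j) exists iff the number of
// in-between samples y[n] with y[n] >= min(y[i], y[j]) is at most L; L = 0 is
// the plain horizontal visibility graph under the strict criterion.
//
// Outward scan from each i with early termination: once the window (i, j)
// holds more than L values >= y[i], no later j' can connect to i.  Proof: if
// y[j'] >= y[i] the blockers (values >= min = y[i]) already exceed L; if
// y[j'] < y[i] then every value >= y[i] is also >= y[j'], so blockers exceed
// L as well.  Within the scan the window is kept as a sorted vector and the
// exact blocker count comes from a binary search, so the result is exact.
// [[Rcpp::export]]
IntegerMatrix lphvg_edges(NumericVector y, int L) {
  const int n = y.size();
  if (n < 2) stop("series too short: need at least 2 samples, got %d", n);
  if (L < 0) stop("penetrable distance L must be >= 0, got %d", L);

  std::vector<int> from, to;
  from.reserve(2 * (L + 1) * n);
  to.reserve(2 * (L + 1) * n);

  std::vector<double> win;  // sorted values strictly between i and j
  for (int i = 0; i < n - 1; ++i) {
    win.clear();
    int ci = 0;  // count of window values >= y[i]
    for (int j = i + 1; j < n; ++j) {
      const double m = std::min(y[i], y[j]);
      const int blockers =
          static_cast<int>(win.end() - std::lower_bound(win.begin(), win.end(), m));
      if (blockers <= L) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
      win.insert(std::lower_bound(win.begin(), win.end(), y[j]), y[j]);
      if (y[j] >= y[i] && ++ci > L) break;
    }
  }

  const int ne = static_cast<int>(from.size());
  IntegerMatrix out(ne, 2);
  for (int e = 0; e < ne; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}
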