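#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Minimum-cost perfect assignment on a square cost matrix (Hungarian
// algorithm, shortest-augmenting-path formulation, O(n^3)). Used for
// frame-to-frame linking; gated (forbidden) pairs carry a large finite
// cost so minimizing total cost yields the maximum-cardinality,
// minimum-cost matching over allowed pairs.

// [[Rcpp::export(name = ".hungarian_cpp")]]
IntegerVector hungarian_cpp(NumericMatrix a) {
  int n = a.nrow();
  if (n != a.ncol()) stop("square matrix required");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector match(n); // match[i] = column assigned to row i (1-based)
  for (int j = 1; j <= n; ++j) match[p[j] - 1] = j;
  return match;
}
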