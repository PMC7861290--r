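#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Length-normalized DTW between two frame sequences (rows = frames).
// Frame cost is Euclidean (rooted by default, squared if requested);
// steps are the three unit moves with weight 1, gamma(1,1) = d(1,1).
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix x, NumericMatrix y, bool squared) {
  const int n = x.nrow(), m = y.nrow(), d = x.ncol();
  if (d != y.ncol()) stop("frame dimension mismatch");
  const double inf = R_PosInf;
  std::vector<double> prev(m), curr(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = x(i, k) - y(j, k);
        s += diff * diff;
      }
      const double cost = squared ? s : std::sqrt(s);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        const double up   = i > 0 ? prev[j] : inf;
        const double left = j > 0 ? curr[j - 1] : inf;
        const double diag = (i > 0 && j > 0) ? prev[j - 1] : inf;
        best = std::min(diag, std::min(up, left));
      }
      curr[j] = cost + best;
    }
    std::swap(prev, curr);
  }
  const double raw = prev[m - 1];
  return List::create(_["raw_cost"] = raw,
                      _["distance"] = raw / (double)(n + m),
                      _["n"] = n, _["m"] = m);
}
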