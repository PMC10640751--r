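#include <Rcpp.h>
using namespace Rcpp;

// Greedy max-min farthest point sampling with the incremental
// nearest-selected-distance update: O(M n) distance evaluations for M
// source points and n selections.  `start` is 0-based; ties broken by the
// lowest index; already-selected points (flagged d2 < 0) are never
// re-selected, so duplicate coordinates are handled.  Returns 0-based
// indices in selection order.
// [[Rcpp::export(name = ".fps_cpp")]]
IntegerVector fps_cpp(NumericMatrix coords, int n, int start) {
  const int m = coords.nrow();
  if (n < 1 || n > m) stop("n out of range");
  if (start < 0 || start >= m) stop("start out of range");
  IntegerVector sel(n);
  std::vector<double> d2(m, R_PosInf);
  int cur = start;
  sel[0] = cur;
  d2[cur] = -1.0;
  for (int i = 1; i < n; ++i) {
    const double cx = coords(cur, 0), cy = coords(cur, 1), cz = coords(cur, 2);
    int far = -1;
    double best = -1.0;
    for (int j = 0; j < m; ++j) {
      if (d2[j] < 0.0) continue;  // already selected
      const double dx = coords(j, 0) - cx;
      const double dy = coords(j, 1) - cy;
      const double dz = coords(j, 2) - cz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < d2[j]) d2[j] = dd;
      if (d2[j] > best) { best = d2[j]; far = j; }
    }
    cur = far;
    sel[i] = cur;
    d2[cur] = -1.0;
  }
  return sel;
}
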