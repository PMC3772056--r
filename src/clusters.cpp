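#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Iterative flood fill over a logical grid; 4- or 8-connectivity.
// Returns labels 1..k (0 = background) in the same nrow x ncol layout.
static void flood(const LogicalMatrix& mask, IntegerMatrix& labels,
                  int r0, int c0, int label, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(r0, c0));
  labels(r0, c0) = label;
  static const int dr4[] = {-1, 1, 0, 0};
  static const int dc4[] = {0, 0, -1, 1};
  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int i = 0; i < nn; ++i) {
      int r = p.first + dr[i], c = p.second + dc[i];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (mask(r, c) && labels(r, c) == 0) {
        labels(r, c) = label;
        stack.push_back(std::make_pair(r, c));
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) && labels(r, c) == 0)
        flood(mask, labels, r, c, ++next, connectivity);
  return labels;
}

// Maximum supra-threshold cluster extents of a t-map under the given
// adjacency. `exclude` marks bins removed from clustering (wavelet edges).
// Returns (max positive-cluster extent, max negative-cluster extent).
// [[Rcpp::export]]
IntegerVector max_cluster_extents(NumericMatrix tmap, double threshold,
                                  int connectivity, LogicalMatrix exclude) {
  const int nr = tmap.nrow(), nc = tmap.ncol();
  IntegerVector out(2);
  LogicalMatrix mask(nr, nc);
  for (int sign = 0; sign < 2; ++sign) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double v = sign == 0 ? tmap(r, c) : -tmap(r, c);
        mask(r, c) = !exclude(r, c) && R_finite(v) && v > threshold;
      }
    IntegerMatrix labels(nr, nc);
    int next = 0, best = 0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (mask(r, c) && labels(r, c) == 0)
          flood(mask, labels, r, c, ++next, connectivity);
    if (next > 0) {
      std::vector<int> counts(next + 1, 0);
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          if (labels(r, c) > 0) ++counts[labels(r, c)];
      for (int i = 1; i <= next; ++i) if (counts[i] > best) best = counts[i];
    }
    out[sign] = best;
  }
  return out;
}
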