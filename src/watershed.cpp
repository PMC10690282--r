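#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling of a logical matrix.
// Labels are assigned in raster-scan order of each component's first pixel,
// so output is deterministic and labels are consecutive from 1.
// [[Rcpp::export(name = ".cc_label4")]]
IntegerMatrix cc_label4(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct PixEntry {
  double prio;     // probability value: higher floods first
  long order;      // insertion counter: FIFO tie-break, deterministic
  int idx;
};

struct PixCompare {
  bool operator()(const PixEntry& a, const PixEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on probability
    return a.order > b.order;                      // earlier insertion wins
  }
};

// Seeded region-growing watershed on a probability map.
// Seeds flood outward in order of decreasing probability (equivalently a
// watershed on the negated map), restricted to `mask`; 4-connectivity.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix prob, IntegerMatrix seeds,
                              LogicalMatrix mask) {
  const int nr = prob.nrow(), nc = prob.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc || mask.nrow() != nr ||
      mask.ncol() != nc)
    stop("probability map, seeds and mask must share one shape");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<PixEntry, std::vector<PixEntry>, PixCompare> pq;
  long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        pq.push({prob(i, j), counter++, i + j * nr});
      }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    PixEntry e = pq.top(); pq.pop();
    int pi = e.idx % nr, pj = e.idx / nr;
    int l = lab(pi, pj);
    for (int k = 0; k < 4; ++k) {
      int qi = pi + di[k], qj = pj + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (!mask(qi, qj) || lab(qi, qj) != 0) continue;
      lab(qi, qj) = l;
      pq.push({prob(qi, qj), counter++, qi + qj * nr});
    }
  }
  return lab;
}
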