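#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Ordering on (squared distance, cell index): smaller distance wins, equal
// distances are broken toward the smaller index.  This total order is what
// makes the whole neighbor graph deterministic.
struct Cand {
  double d2;
  int idx; // 0-based
};
static inline bool worse(const Cand &a, const Cand &b) {
  if (a.d2 != b.d2) return a.d2 > b.d2;
  return a.idx > b.idx;
}
struct CandWorse {
  bool operator()(const Cand &a, const Cand &b) const { return worse(b, a); }
};

// Exact kNN by full scan with a bounded max-heap per query cell.
// coords: n x d (row = cell).  m: number of neighbors to keep (excludes
// self).  Squared distances are accumulated coordinate-wise (no Gram-matrix
// trick) so that geometrically equal distances compare equal in floating
// point and the index tie-break applies.
// [[Rcpp::export(name = ".exact_knn_cpp")]]
List exact_knn_cpp(NumericMatrix coords, int m) {
  const int n = coords.nrow(), d = coords.ncol();
  if (m > n - 1) m = n - 1;
  IntegerMatrix idx(n, m);
  NumericMatrix dist(n, m);

  // column-major R matrix: copy to row-major buffer for cache locality
  std::vector<double> X((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      X[(size_t)i * d + j] = coords(i, j);

  std::vector<Cand> heap;
  heap.reserve(m + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    const double *xi = &X[(size_t)i * d];
    double bound = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *xj = &X[(size_t)j * d];
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = xi[t] - xj[t];
        s += diff * diff;
        if (s > bound) break; // cannot enter the heap
      }
      if (s > bound) continue;
      Cand c{s, j};
      if ((int)heap.size() < m) {
        heap.push_back(c);
        std::push_heap(heap.begin(), heap.end(), CandWorse());
        if ((int)heap.size() == m) bound = heap.front().d2;
      } else if (worse(heap.front(), c)) {
        std::pop_heap(heap.begin(), heap.end(), CandWorse());
        heap.back() = c;
        std::push_heap(heap.begin(), heap.end(), CandWorse());
        bound = heap.front().d2;
      }
    }
    std::sort(heap.begin(), heap.end(),
              [](const Cand &a, const Cand &b) { return worse(b, a); });
    for (int t = 0; t < (int)heap.size(); ++t) {
      idx(i, t) = heap[t].idx + 1; // 1-based for R
      dist(i, t) = std::sqrt(heap[t].d2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
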