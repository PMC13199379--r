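// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Blocked exact kNN for large n: candidate generation by the Gram-matrix
// identity |x-y|^2 = |x|^2 + |y|^2 - 2<x,y> (BLAS gemm), followed by exact
// coordinate-wise recomputation of the candidate distances so that the
// final ordering -- ascending (squared distance, cell index) -- is
// identical to the naive full scan.  A candidate slack absorbs the
// floating-point noise of the Gram form at the selection boundary.
// [[Rcpp::export(name = ".exact_knn_blocked_cpp")]]
List exact_knn_blocked_cpp(const arma::mat &coords, int m, int slack = 16,
                           int block = 256) {
  const int n = coords.n_rows, d = coords.n_cols;
  if (m > n - 1) m = n - 1;
  const int cand = std::min(n - 1, m + slack);
  IntegerMatrix idx(n, m);
  NumericMatrix dist(n, m);

  arma::vec sq = arma::sum(arma::square(coords), 1);
  const arma::mat Xt = coords.t(); // d x n, column = cell

  std::vector<std::pair<double, int> > buf(n), exact(cand);
  for (int lo = 0; lo < n; lo += block) {
    const int hi = std::min(lo + block, n);
    arma::mat G = coords.rows(lo, hi - 1) * Xt; // (hi-lo) x n
    for (int i = lo; i < hi; ++i) {
      const double *g = G.colptr(0) + (i - lo); // row i-lo, stride hi-lo
      const int stride = hi - lo;
      int nb = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        buf[nb++] = std::make_pair(sq[i] + sq[j] - 2.0 * g[(size_t)j * stride],
                                   j);
      }
      std::nth_element(buf.begin(), buf.begin() + cand - 1, buf.begin() + nb);
      // exact recomputation of the candidate distances
      const double *xi = Xt.colptr(i);
      for (int t = 0; t < cand; ++t) {
        const int j = buf[t].second;
        const double *xj = Xt.colptr(j);
        double s = 0.0;
        for (int a = 0; a < d; ++a) {
          const double diff = xi[a] - xj[a];
          s += diff * diff;
        }
        exact[t] = std::make_pair(s, j);
      }
      std::sort(exact.begin(), exact.end());
      for (int t = 0; t < m; ++t) {
        idx(i, t) = exact[t].second + 1;
        dist(i, t) = std::sqrt(exact[t].first);
      }
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
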