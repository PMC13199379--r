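#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// nn: n x (k_param - 1) matrix of 1-based neighbor indices, ascending by
// (distance, index).  All scores below count directed edges including the
// self-edge I_{i,i} = 1.

// Per-cell neighborhood connectivity: for the size-k neighborhood S of each
// cell (the cell plus its k-1 nearest neighbors), count edges i -> j with
// i, j in S, where each member i contributes its self-edge and its own k-1
// nearest out-edges; divide by k*k.
// [[Rcpp::export(name = ".q_scores_cpp")]]
NumericVector q_scores_cpp(IntegerMatrix nn, int k) {
  const int n = nn.nrow();
  NumericVector q(n);
  std::vector<int> S(k);
  for (int c = 0; c < n; ++c) {
    S[0] = c + 1;
    for (int t = 0; t < k - 1; ++t) S[t + 1] = nn(c, t);
    int count = k; // every member's self-edge lands in S
    for (int a = 0; a < k; ++a) {
      const int i = S[a] - 1;
      for (int t = 0; t < k - 1; ++t) {
        const int j = nn(i, t);
        for (int b = 0; b < k; ++b)
          if (S[b] == j) { ++count; break; }
      }
    }
    q[c] = (double)count / ((double)k * (double)k);
  }
  return q;
}

// Cluster connectivity Qc: members are 1-based cell indices, keff is the
// effective out-edge budget (min(n_members, k.param)); counts the self-edge
// plus each member's keff-1 nearest out-edges that stay inside the cluster,
// normalized by n_members * keff.
// [[Rcpp::export(name = ".cluster_q_cpp")]]
double cluster_q_cpp(IntegerMatrix nn, IntegerVector members, int keff) {
  const int n = nn.nrow();
  const int nc = members.size();
  std::vector<char> inC(n, 0);
  for (int a = 0; a < nc; ++a) inC[members[a] - 1] = 1;
  long count = nc; // self-edges
  for (int a = 0; a < nc; ++a) {
    const int i = members[a] - 1;
    for (int t = 0; t < keff - 1; ++t)
      if (inC[nn(i, t) - 1]) ++count;
  }
  return (double)count / ((double)nc * (double)keff);
}

// One synchronous round of kNN majority voting: each cell's new label is the
// modal label over itself and its vote_k - 1 nearest neighbors; a tie for
// the mode keeps the current label.
// [[Rcpp::export(name = ".vote_round_cpp")]]
IntegerVector vote_round_cpp(IntegerMatrix nn, IntegerVector labels,
                             int vote_k) {
  const int n = nn.nrow();
  IntegerVector out(n);
  std::vector<int> lab(vote_k), cnt(vote_k);
  for (int c = 0; c < n; ++c) {
    lab[0] = labels[c];
    for (int t = 0; t < vote_k - 1; ++t) lab[t + 1] = labels[nn(c, t) - 1];
    int m = 0;
    for (int a = 0; a < vote_k; ++a) {
      bool seen = false;
      for (int b = 0; b < m; ++b)
        if (lab[b] == lab[a]) { ++cnt[b]; seen = true; break; }
      if (!seen) { lab[m] = lab[a]; cnt[m] = 1; ++m; }
    }
    int best = 0, bestCnt = -1, ties = 0;
    for (int b = 0; b < m; ++b) {
      if (cnt[b] > bestCnt) { bestCnt = cnt[b]; best = b; ties = 1; }
      else if (cnt[b] == bestCnt) ++ties;
    }
    out[c] = (ties > 1) ? labels[c] : lab[best];
  }
  return out;
}
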