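#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  double sum;
  std::vector<int> idx; // 0-based rank positions, strictly increasing
};

struct NodeCmp {
  // max-heap on sum; ties broken lexicographically (smaller index vector
  // first) so enumeration order is fully deterministic
  bool operator()(const Node &a, const Node &b) const {
    if (a.sum != b.sum) return a.sum < b.sum;
    return a.idx > b.idx;
  }
};

} // namespace

// Best-first enumeration of K-subsets of rank positions in non-increasing
// order of summed rank mass, truncated at `limit`.  `masses` must be sorted
// non-increasing (rank masses are, by construction).  Successors of a
// subset move one member to the next rank position; with masses sorted,
// every successor has sum <= its parent, so a best-first frontier visits
// subsets in global order.
// [[Rcpp::export(name = ".cpp_enumerate_subsets")]]
IntegerMatrix cpp_enumerate_subsets(NumericVector masses, int K, int limit) {
  const int n = masses.size();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K = %d exceeds the %d available rank positions", K, n);
  if (limit < 1) stop("limit must be >= 1");
  for (int i = 1; i < n; ++i)
    if (masses[i] > masses[i - 1] + 1e-12)
      stop("rank masses must be sorted in non-increasing order");

  std::priority_queue<Node, std::vector<Node>, NodeCmp> heap;
  std::set<std::vector<int>> seen;

  Node first;
  first.idx.resize(K);
  first.sum = 0.0;
  for (int i = 0; i < K; ++i) { first.idx[i] = i; first.sum += masses[i]; }
  heap.push(first);
  seen.insert(first.idx);

  std::vector<std::vector<int>> out;
  out.reserve(limit);
  while (!heap.empty() && (int)out.size() < limit) {
    Node cur = heap.top();
    heap.pop();
    out.push_back(cur.idx);
    for (int i = K - 1; i >= 0; --i) {
      int nxt = cur.idx[i] + 1;
      if (nxt >= n) continue;
      if (i < K - 1 && nxt >= cur.idx[i + 1]) continue;
      Node suc = cur;
      suc.sum += masses[nxt] - masses[suc.idx[i]];
      suc.idx[i] = nxt;
      if (seen.insert(suc.idx).second) heap.push(suc);
    }
  }

  IntegerMatrix res(out.size(), K);
  for (size_t r = 0; r < out.size(); ++r)
    for (int c = 0; c < K; ++c)
      res(r, c) = out[r][c] + 1; // 1-based ranks
  return res;
}
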