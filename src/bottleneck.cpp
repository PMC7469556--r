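#include <Rcpp.h>
using namespace Rcpp;

// Bottleneck centrality over an undirected simple graph.
//
// For every root s a BFS shortest-path tree T_s is built over s's
// component, with the parent of each node fixed deterministically as the
// lowest-index neighbour among its shortest-path predecessors. A node v
// scores 1 from root s iff its subtree in T_s (counting v itself) holds
// more than |V(T_s)|/4 nodes; the root therefore always scores from its
// own tree. BN(v) is the sum over all roots.
//
// adj: 0-based adjacency list, one integer vector per node.

// [[Rcpp::export]]
IntegerVector bottleneck_scores(List adj) {
  const int n = adj.size();
  std::vector< std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    A[i] = as< std::vector<int> >(adj[i]);
    std::sort(A[i].begin(), A[i].end());
  }
  IntegerVector bn(n);
  std::vector<int> dist(n), queue(n), subtree(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    queue[tail++] = s;
    dist[s] = 0;
    while (head < tail) {
      const int v = queue[head++];
      for (int w : A[v]) if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[tail++] = w; }
    }
    const int tree_n = tail;  // size of s's component
    for (int i = 0; i < tree_n; ++i) subtree[queue[i]] = 1;
    // queue is in nondecreasing distance order; accumulate leaves upward
    for (int i = tree_n - 1; i > 0; --i) {
      const int v = queue[i];
      int parent = -1;
      for (int w : A[v]) if (dist[w] == dist[v] - 1) { parent = w; break; }
      subtree[parent] += subtree[v];
    }
    for (int i = 0; i < tree_n; ++i) {
      const int v = queue[i];
      if (4 * subtree[v] > tree_n) ++bn[v];  // integer form of subtree > |T|/4
    }
  }
  return bn;
}
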