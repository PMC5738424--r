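// Binary undirected graph primitives used in the topology pipeline.
// All-pairs shortest paths by breadth-first search on adjacency lists;
// efficiency follows the Latora-Marchiori convention (unreachable pairs
// contribute 0).  The degree-preserving null model is the classic
// double-edge swap, driven by R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <queue>
using namespace Rcpp;

namespace {

typedef std::vector<std::vector<int> > AdjList;

AdjList adj_from_matrix(const LogicalMatrix& A) {
  const int n = A.nrow();
  AdjList adj(n);
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i)
      if (A(i, j)) { adj[i].push_back(j); adj[j].push_back(i); }
  return adj;
}

// BFS distances from src; -1 = unreachable
void bfs(const AdjList& adj, int src, std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    const int u = q.front(); q.pop();
    for (size_t k = 0; k < adj[u].size(); ++k) {
      const int v = adj[u][k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

// mean over ordered pairs of 1/d (== mean over unordered pairs by symmetry)
double global_eff(const AdjList& adj) {
  const int n = (int)adj.size();
  if (n < 2) return 0.0;
  std::vector<int> dist(n);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) s += 1.0 / dist[j];
  }
  return s / ((double)n * (n - 1));
}

}  // namespace

// [[Rcpp::export]]
double eff_global_cpp(LogicalMatrix A) {
  return global_eff(adj_from_matrix(A));
}

// [[Rcpp::export]]
NumericVector eff_nodal_cpp(LogicalMatrix A) {
  AdjList adj = adj_from_matrix(A);
  const int n = A.nrow();
  NumericVector out(n);
  if (n < 2) return out;
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist);
    double s = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) s += 1.0 / dist[j];
    out[i] = s / (n - 1);
  }
  return out;
}

// mean over nodes of the global efficiency of the neighbour-induced
// subgraph; neighbourhoods with < 2 nodes score 0
// [[Rcpp::export]]
double eff_local_cpp(LogicalMatrix A) {
  AdjList adj = adj_from_matrix(A);
  const int n = A.nrow();
  if (n == 0) return 0.0;
  std::vector<int> pos(n, -1);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = adj[i];
    const int k = (int)nb.size();
    if (k < 2) continue;
    for (int a = 0; a < k; ++a) pos[nb[a]] = a;
    AdjList sub(k);
    for (int a = 0; a < k; ++a) {
      const std::vector<int>& na = adj[nb[a]];
      for (size_t t = 0; t < na.size(); ++t) {
        const int p = pos[na[t]];
        if (p >= 0 && p != a) sub[a].push_back(p);
      }
    }
    for (int a = 0; a < k; ++a) pos[nb[a]] = -1;
    total += global_eff(sub);
  }
  return total / n;
}

// [[Rcpp::export]]
bool connected_cpp(LogicalMatrix A) {
  const int n = A.nrow();
  if (n <= 1) return true;
  AdjList adj = adj_from_matrix(A);
  std::vector<int> dist(n);
  bfs(adj, 0, dist);
  for (int i = 0; i < n; ++i)
    if (dist[i] < 0) return false;
  return true;
}

// Degree-preserving rewiring by attempted double-edge swaps.
// edges: m x 2 (0-based); returns rewired m x 2 edge list and the number
// of accepted swaps (attribute "accepted").
// [[Rcpp::export]]
IntegerMatrix rewire_degseq_cpp(IntegerMatrix edges, int n, int niter) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<long long> eset;
  eset.reserve(m * 2);
  auto key = [n](int i, int j) {
    return (long long)std::min(i, j) * n + std::max(i, j);
  };
  for (int e = 0; e < m; ++e) {
    ea[e] = edges(e, 0); eb[e] = edges(e, 1);
    eset.insert(key(ea[e], eb[e]));
  }
  int accepted = 0;
  if (m >= 2) {
    for (int t = 0; t < niter; ++t) {
      const int e1 = (int)(unif_rand() * m);
      const int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      if (unif_rand() < 0.5) std::swap(c, d);
      // proposed: (a,d), (c,b)
      if (a == c || a == d || b == c || b == d) continue;
      if (eset.count(key(a, d)) || eset.count(key(c, b))) continue;
      eset.erase(key(a, b));
      eset.erase(key(c, d));
      eset.insert(key(a, d));
      eset.insert(key(c, b));
      ea[e1] = a; eb[e1] = d;
      ea[e2] = c; eb[e2] = b;
      ++accepted;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = ea[e]; out(e, 1) = eb[e]; }
  out.attr("accepted") = accepted;
  return out;
}
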