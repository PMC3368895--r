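// Binary undirected graph metrics and degree-preserving rewiring.
// Adjacency matrices are dense integer 0/1 with zero diagonal; all routines
// assume (and some check) symmetry. Randomness comes from R's RNG so that
// set.seed() on the R side fully determines output.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

static std::vector<std::vector<int> > adj_list(const IntegerMatrix &A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// BFS distances from a single source over an adjacency list; -1 = unreachable
static void bfs_from(const std::vector<std::vector<int> > &nb, int src,
                     std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (size_t k = 0; k < nb[u].size(); ++k) {
      int v = nb[u][k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  NumericMatrix D(n, n);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs_from(nb, i, dist);
    for (int j = 0; j < n; ++j)
      D(i, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return D;
}

// [[Rcpp::export]]
bool cpp_connected(IntegerMatrix A) {
  const int n = A.nrow();
  if (n == 0) return true;
  std::vector<std::vector<int> > nb = adj_list(A);
  std::vector<int> dist(n);
  bfs_from(nb, 0, dist);
  for (int j = 0; j < n; ++j) if (dist[j] < 0) return false;
  return true;
}

// Per-node clustering: fraction of existing edges among the node's neighbors.
// Nodes with degree < 2 contribute 0.
// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  NumericVector ci(n);
  for (int i = 0; i < n; ++i) {
    const int k = (int)nb[i].size();
    if (k < 2) { ci[i] = 0.0; continue; }
    int e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++e;
    ci[i] = 2.0 * e / ((double)k * (k - 1));
  }
  return ci;
}

// Global efficiency of a subgraph given by node indices (within A):
// mean over pairs of 1/d, with 1/Inf = 0.
static double sub_global_eff(const IntegerMatrix &A, const std::vector<int> &nodes) {
  const int m = (int)nodes.size();
  if (m < 2) return 0.0;
  // local adjacency list
  std::vector<std::vector<int> > nb(m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && A(nodes[a], nodes[b]) != 0) nb[a].push_back(b);
  std::vector<int> dist(m);
  double s = 0.0;
  for (int a = 0; a < m; ++a) {
    bfs_from(nb, a, dist);
    for (int b = 0; b < m; ++b)
      if (b != a && dist[b] > 0) s += 1.0 / dist[b];
  }
  return s / ((double)m * (m - 1));
}

// Nodal local efficiency: global efficiency of the subgraph induced by the
// neighbors of i (i itself removed); 0 when degree < 2.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  NumericVector el(n);
  for (int i = 0; i < n; ++i)
    el[i] = ((int)nb[i].size() < 2) ? 0.0 : sub_global_eff(A, nb[i]);
  return el;
}

// Fast path used by the null ensemble: mean clustering and characteristic
// path length (Inf when disconnected) in one pass.
// [[Rcpp::export]]
NumericVector cpp_cnet_lnet(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    const int k = (int)nb[i].size();
    if (k < 2) continue;
    int e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b]) != 0) ++e;
    csum += 2.0 * e / ((double)k * (k - 1));
  }
  std::vector<int> dist(n);
  double lsum = 0.0;
  bool disconnected = false;
  for (int i = 0; i < n && !disconnected; ++i) {
    bfs_from(nb, i, dist);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist[j] < 0) { disconnected = true; break; }
      lsum += dist[j];
    }
  }
  NumericVector out(2);
  out[0] = n > 0 ? csum / n : 0.0;
  out[1] = disconnected ? R_PosInf
                        : (n > 1 ? lsum / ((double)n * (n - 1)) : 0.0);
  return out;
}

struct EdgeList {
  std::vector<int> a, b;
};

static EdgeList edges_of(const IntegerMatrix &A) {
  EdgeList e;
  const int n = A.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) { e.a.push_back(i); e.b.push_back(j); }
  return e;
}

static bool connected_adj(const IntegerMatrix &A) { return cpp_connected(A); }

// Degree-preserving double-edge swaps on a working copy of A.
// Returns the number of accepted swaps; gives up after attempt_cap proposals.
static int do_swaps(IntegerMatrix &A, EdgeList &e, int target, double attempt_cap) {
  const int m = (int)e.a.size();
  if (m < 2) return 0;
  int accepted = 0;
  double attempts = 0.0;
  while (accepted < target && attempts < attempt_cap) {
    attempts += 1.0;
    int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = e.a[i], b = e.b[i], c = e.a[j], d = e.b[j];
    if (unif_rand() < 0.5) std::swap(c, d);   // unbiased pairing choice
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == c || a == d || b == c || b == d) continue;
    if (A(a, d) != 0 || A(c, b) != 0) continue;
    A(a, b) = A(b, a) = 0;
    A(c, d) = A(d, c) = 0;
    A(a, d) = A(d, a) = 1;
    A(c, b) = A(b, c) = 1;
    e.a[i] = a; e.b[i] = d;
    e.a[j] = c; e.b[j] = b;
    ++accepted;
  }
  return accepted;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix A, double swaps_factor,
                         bool enforce_connected, int max_connect_retries) {
  IntegerMatrix W = clone(A);
  EdgeList e = edges_of(W);
  const int m = (int)e.a.size();
  const int target = (int)std::ceil(swaps_factor * m);
  if (m < 2 || target == 0) return W;
  do_swaps(W, e, target, 200.0 * target + 1000.0);
  if (enforce_connected && connected_adj(A)) {
    int tries = 0;
    while (!connected_adj(W)) {
      if (++tries > max_connect_retries)
        stop("could not obtain a connected degree-preserving rewiring after %d retries; increase swaps_factor", max_connect_retries);
      do_swaps(W, e, m, 200.0 * m + 1000.0);
    }
  }
  return W;
}

// ---- fast edge-list machinery for the null ensemble ----

struct Graph {
  int n;
  std::vector<int> ea, eb;          // edge endpoints
  std::vector<char> bits;           // dense adjacency lookup
  bool has(int i, int j) const { return bits[(size_t)i * n + j] != 0; }
  void set(int i, int j, char v) {
    bits[(size_t)i * n + j] = v;
    bits[(size_t)j * n + i] = v;
  }
  std::vector<std::vector<int> > neighbors() const {
    std::vector<std::vector<int> > nb(n);
    for (size_t e = 0; e < ea.size(); ++e) {
      nb[ea[e]].push_back(eb[e]);
      nb[eb[e]].push_back(ea[e]);
    }
    return nb;
  }
};

static Graph graph_from_adj(const IntegerMatrix &A) {
  Graph g;
  g.n = A.nrow();
  g.bits.assign((size_t)g.n * g.n, 0);
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (A(i, j) != 0) {
        g.ea.push_back(i); g.eb.push_back(j);
        g.set(i, j, 1);
      }
  return g;
}

static bool graph_connected(const Graph &g) {
  if (g.n == 0) return true;
  std::vector<std::vector<int> > nb = g.neighbors();
  std::vector<int> dist(g.n);
  bfs_from(nb, 0, dist);
  for (int j = 0; j < g.n; ++j) if (dist[j] < 0) return false;
  return true;
}

// mean clustering and characteristic path length from an edge-list graph
static void graph_cnet_lnet(const Graph &g, double &cnet, double &lnet) {
  std::vector<std::vector<int> > nb = g.neighbors();
  double csum = 0.0;
  for (int i = 0; i < g.n; ++i) {
    const int k = (int)nb[i].size();
    if (k < 2) continue;
    int e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (g.has(nb[i][a], nb[i][b])) ++e;
    csum += 2.0 * e / ((double)k * (k - 1));
  }
  cnet = g.n > 0 ? csum / g.n : 0.0;
  std::vector<int> dist(g.n);
  double lsum = 0.0;
  for (int i = 0; i < g.n; ++i) {
    bfs_from(nb, i, dist);
    for (int j = 0; j < g.n; ++j) {
      if (j == i) continue;
      if (dist[j] < 0) { lnet = R_PosInf; return; }
      lsum += dist[j];
    }
  }
  lnet = g.n > 1 ? lsum / ((double)g.n * (g.n - 1)) : 0.0;
}

static int graph_swaps(Graph &g, int target, double attempt_cap) {
  const int m = (int)g.ea.size();
  if (m < 2) return 0;
  int accepted = 0;
  double attempts = 0.0;
  while (accepted < target && attempts < attempt_cap) {
    attempts += 1.0;
    int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = g.ea[i], b = g.eb[i], c = g.ea[j], d = g.eb[j];
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.set(a, b, 0); g.set(c, d, 0);
    g.set(a, d, 1); g.set(c, b, 1);
    g.ea[i] = a; g.eb[i] = d;
    g.ea[j] = c; g.eb[j] = b;
    ++accepted;
  }
  return accepted;
}

// sigma ensemble against n_nulls rewired graphs (nulls forced connected
// when the source is). Returns per-null C_rand, L_rand and sigma (NA when
// a null has zero clustering).
// [[Rcpp::export]]
List cpp_sigma_ensemble(IntegerMatrix A, int n_nulls, double swaps_factor,
                        int max_connect_retries) {
  Graph src = graph_from_adj(A);
  double c0, l0;
  graph_cnet_lnet(src, c0, l0);
  const bool src_conn = graph_connected(src);
  const int m = (int)src.ea.size();
  const int target = (int)std::ceil(swaps_factor * m);
  NumericVector cr(n_nulls), lr(n_nulls), sig(n_nulls);
  for (int r = 0; r < n_nulls; ++r) {
    Graph w = src;
    graph_swaps(w, target, 200.0 * target + 1000.0);
    if (src_conn) {
      int tries = 0;
      while (!graph_connected(w)) {
        if (++tries > max_connect_retries)
          stop("could not obtain a connected degree-preserving rewiring after %d retries; increase swaps_factor", max_connect_retries);
        graph_swaps(w, m, 200.0 * m + 1000.0);
      }
    }
    double cn, ln;
    graph_cnet_lnet(w, cn, ln);
    cr[r] = cn; lr[r] = ln;
    if (cn <= 0.0 || !R_finite(ln) || ln <= 0.0) {
      sig[r] = NA_REAL;
    } else {
      sig[r] = (c0 / cn) / (l0 / ln);
    }
  }
  return List::create(_["c_net"] = c0, _["l_net"] = l0,
                      _["c_rand"] = cr, _["l_rand"] = lr, _["sigma"] = sig);
}

// Metrics along a nested sequence of edge counts. ord0 is the 0-based
// upper-triangle edge order (strongest first, ties already broken upstream)
// given as two index vectors. For each requested edge count the first E
// edges are present. Returns a matrix with columns
// (k_net, c_net, l_net, e_global, e_local, connected).
// [[Rcpp::export]]
NumericMatrix cpp_metrics_nested(int n, IntegerVector ord_i, IntegerVector ord_j,
                                 IntegerVector edge_counts, bool with_local) {
  const int nd = edge_counts.size();
  NumericMatrix out(nd, 6);
  IntegerMatrix A(n, n);
  int placed = 0;
  for (int d = 0; d < nd; ++d) {
    const int E = edge_counts[d];
    if (E < placed) stop("edge_counts must be non-decreasing");
    if (E > ord_i.size()) stop("edge count exceeds available edges");
    for (; placed < E; ++placed) {
      A(ord_i[placed], ord_j[placed]) = 1;
      A(ord_j[placed], ord_i[placed]) = 1;
    }
    NumericVector cl = cpp_cnet_lnet(A);
    NumericMatrix D = cpp_bfs_distances(A);
    double es = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j && R_finite(D(i, j)) && D(i, j) > 0) es += 1.0 / D(i, j);
    const double eg = n > 1 ? es / ((double)n * (n - 1)) : 0.0;
    double el = 0.0;
    if (with_local) {
      NumericVector eli = cpp_local_efficiency(A);
      el = mean(eli);
    } else {
      el = NA_REAL;
    }
    out(d, 0) = 2.0 * E / (double)n;
    out(d, 1) = cl[0];
    out(d, 2) = cl[1];
    out(d, 3) = eg;
    out(d, 4) = el;
    out(d, 5) = cpp_connected(A) ? 1.0 : 0.0;
  }
  return out;
}
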