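#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Binary undirected graph metric core. All functions take a 1-based
// edge list; node count is passed explicitly so isolated nodes are
// kept. Conventions: local clustering 0 for degree < 2; Lp = mean
// shortest path over pairs in the largest connected component;
// efficiencies treat unreachable pairs as 0; betweenness is exact
// unnormalized Brandes; assortativity is the Pearson correlation of
// degrees over edge endpoints (Newman's r).

typedef std::vector<std::vector<int> > AdjList;

static AdjList build_adj(const IntegerMatrix& edges, int n) {
  AdjList adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  return adj;
}

static void bfs(const AdjList& adj, int s, std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  std::queue<int> q;
  dist[s] = 0;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

// mean local clustering (degree<2 -> 0)
static double clustering_mean(const AdjList& adj, int n) {
  std::vector<std::vector<bool> > isnb(n, std::vector<bool>(n, false));
  for (int u = 0; u < n; ++u)
    for (size_t k = 0; k < adj[u].size(); ++k) isnb[u][adj[u][k]] = true;
  double total = 0.0;
  for (int u = 0; u < n; ++u) {
    int d = (int)adj[u].size();
    if (d < 2) continue;
    int tri = 0;
    for (int a = 0; a < d; ++a)
      for (int b = a + 1; b < d; ++b)
        if (isnb[adj[u][a]][adj[u][b]]) ++tri;
    total += 2.0 * tri / ((double)d * (d - 1));
  }
  return total / n;
}

// characteristic path length within the largest connected component
static double char_path_length(const AdjList& adj, int n) {
  std::vector<int> comp(n, -1);
  std::vector<int> dist(n);
  int ncomp = 0;
  std::vector<int> csize;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    bfs(adj, s, dist);
    int sz = 0;
    for (int v = 0; v < n; ++v)
      if (dist[v] >= 0 && comp[v] < 0) { comp[v] = ncomp; ++sz; }
    csize.push_back(sz);
    ++ncomp;
  }
  int big = (int)(std::max_element(csize.begin(), csize.end()) -
                  csize.begin());
  if (csize[big] < 2) return NA_REAL;
  double sum = 0.0;
  long long npairs = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != big) continue;
    bfs(adj, s, dist);
    for (int t = s + 1; t < n; ++t) {
      if (comp[t] != big) continue;
      sum += dist[t];
      ++npairs;
    }
  }
  return sum / npairs;
}

// global efficiency of the subgraph induced by `nodes` (original ids)
static double subgraph_efficiency(const AdjList& adj,
                                  const std::vector<int>& nodes) {
  int m = (int)nodes.size();
  if (m < 2) return 0.0;
  std::vector<int> local_id(adj.size(), -1);
  for (int k = 0; k < m; ++k) local_id[nodes[k]] = k;
  AdjList sub(m);
  for (int k = 0; k < m; ++k) {
    int u = nodes[k];
    for (size_t a = 0; a < adj[u].size(); ++a) {
      int lv = local_id[adj[u][a]];
      if (lv >= 0) sub[k].push_back(lv);
    }
  }
  std::vector<int> dist(m);
  double sum = 0.0;
  for (int s = 0; s < m; ++s) {
    bfs(sub, s, dist);
    for (int t = 0; t < m; ++t)
      if (t != s && dist[t] > 0) sum += 1.0 / dist[t];
  }
  return sum / ((double)m * (m - 1));
}

static double assortativity_degree(const IntegerMatrix& edges,
                                   const std::vector<int>& deg) {
  int m = edges.nrow();
  double sjk = 0, sj = 0, sj2 = 0;
  for (int e = 0; e < m; ++e) {
    double j = deg[edges(e, 0) - 1], k = deg[edges(e, 1) - 1];
    sjk += j * k;
    sj += 0.5 * (j + k);
    sj2 += 0.5 * (j * j + k * k);
  }
  double num = sjk / m - (sj / m) * (sj / m);
  double den = sj2 / m - (sj / m) * (sj / m);
  if (den == 0.0) return NA_REAL;
  return num / den;
}

// Brandes (2001) exact betweenness, unweighted, unnormalized
static std::vector<double> betweenness_brandes(const AdjList& adj, int n) {
  std::vector<double> bc(n, 0.0);
  std::vector<int> dist(n), sigma(n);
  std::vector<double> delta(n);
  std::vector<int> stack;
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    stack.clear();
    for (int v = 0; v < n; ++v) {
      pred[v].clear();
      dist[v] = -1;
      sigma[v] = 0;
      delta[v] = 0.0;
    }
    dist[s] = 0;
    sigma[s] = 1;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      stack.push_back(u);
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
        if (dist[v] == dist[u] + 1) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int k = (int)stack.size() - 1; k >= 0; --k) {
      int w = stack[k];
      for (size_t a = 0; a < pred[w].size(); ++a) {
        int v = pred[w][a];
        delta[v] += ((double)sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int v = 0; v < n; ++v) bc[v] /= 2.0;  // each pair counted twice
  return bc;
}

// in-place double-edge-swap rewiring (R RNG); counts successful swaps
static void rewire_inplace(std::vector<int>& a, std::vector<int>& b,
                           std::unordered_set<long long>& present,
                           int n_swaps, int max_attempts_factor) {
  int m = (int)a.size();
  long long K = 1LL << 32;
  long long max_attempts = (long long)max_attempts_factor * n_swaps;
  long long attempts = 0;
  int done = 0;
  while (done < n_swaps && attempts < max_attempts) {
    ++attempts;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int u1 = a[e1], v1 = b[e1], u2 = a[e2], v2 = b[e2];
    if (unif_rand() < 0.5) std::swap(u2, v2);
    if (u1 == v2 || u2 == v1) continue;
    int p1 = std::min(u1, v2), q1 = std::max(u1, v2);
    int p2 = std::min(u2, v1), q2 = std::max(u2, v1);
    long long k1 = (long long)p1 * K + q1;
    long long k2 = (long long)p2 * K + q2;
    if (k1 == k2) continue;
    if (present.count(k1) || present.count(k2)) continue;
    present.erase((long long)a[e1] * K + b[e1]);
    present.erase((long long)a[e2] * K + b[e2]);
    a[e1] = p1; b[e1] = q1;
    a[e2] = p2; b[e2] = q2;
    present.insert(k1);
    present.insert(k2);
    ++done;
  }
}

// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix edges, int n_nodes,
                       bool include_nodal = true) {
  AdjList adj = build_adj(edges, n_nodes);
  std::vector<int> deg(n_nodes);
  for (int v = 0; v < n_nodes; ++v) deg[v] = (int)adj[v].size();
  double cp = clustering_mean(adj, n_nodes);
  double lp = char_path_length(adj, n_nodes);
  // global + nodal efficiency from one BFS sweep
  std::vector<int> dist(n_nodes);
  std::vector<double> nodal_eff(n_nodes, 0.0);
  double eglob = 0.0;
  for (int s = 0; s < n_nodes; ++s) {
    bfs(adj, s, dist);
    double row = 0.0;
    for (int t = 0; t < n_nodes; ++t)
      if (t != s && dist[t] > 0) row += 1.0 / dist[t];
    nodal_eff[s] = row / (n_nodes - 1);
    eglob += row;
  }
  eglob /= (double)n_nodes * (n_nodes - 1);
  double eloc = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    eloc += subgraph_efficiency(adj, std::vector<int>(adj[v].begin(),
                                                      adj[v].end()));
  eloc /= n_nodes;
  double assort = assortativity_degree(edges, deg);
  List out = List::create(
    _["Cp"] = cp, _["Lp"] = lp, _["Eglob"] = eglob, _["Eloc"] = eloc,
    _["assortativity"] = assort);
  if (include_nodal) {
    std::vector<double> bc = betweenness_brandes(adj, n_nodes);
    out["degree"] = IntegerVector(deg.begin(), deg.end());
    out["betweenness"] = NumericVector(bc.begin(), bc.end());
    out["nodal_efficiency"] = NumericVector(nodal_eff.begin(),
                                            nodal_eff.end());
  }
  return out;
}

// Mean Cp and Lp over n_null Maslov-Sneppen rewired null graphs,
// 10|E| successful swaps each (spec'd via n_swaps).
// [[Rcpp::export]]
List null_metrics_cpp(IntegerMatrix edges, int n_nodes, int n_null,
                      int n_swaps, int max_attempts_factor = 100) {
  int m = edges.nrow();
  if (m < 2) stop("null model needs at least 2 edges");
  long long K = 1LL << 32;
  double cp_sum = 0.0, lp_sum = 0.0;
  int lp_n = 0;
  for (int b = 0; b < n_null; ++b) {
    std::vector<int> a(m), bb(m);
    std::unordered_set<long long> present;
    present.reserve(2 * m);
    for (int e = 0; e < m; ++e) {
      int u = edges(e, 0), v = edges(e, 1);
      if (u > v) std::swap(u, v);
      a[e] = u; bb[e] = v;
      present.insert((long long)u * K + v);
    }
    rewire_inplace(a, bb, present, n_swaps, max_attempts_factor);
    IntegerMatrix re(m, 2);
    for (int e = 0; e < m; ++e) { re(e, 0) = a[e]; re(e, 1) = bb[e]; }
    AdjList adj = build_adj(re, n_nodes);
    cp_sum += clustering_mean(adj, n_nodes);
    double lp = char_path_length(adj, n_nodes);
    if (!ISNAN(lp)) { lp_sum += lp; ++lp_n; }
  }
  return List::create(
    _["Cp_rand"] = cp_sum / n_null,
    _["Lp_rand"] = lp_n > 0 ? lp_sum / lp_n : NA_REAL);
}
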