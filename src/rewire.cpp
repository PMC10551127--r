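#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Maslov-Sneppen degree-preserving rewiring by double-edge swaps.
// Picks two distinct edges (a,b), (c,d) and replaces them with (a,d),
// (c,b); a swap is rejected (and retried) if it would create a self-loop
// or a multi-edge. Counts *successful* swaps up to n_swaps, giving up
// after max_attempts_factor * n_swaps attempts (graphs whose degree
// sequence admits no rewiring, e.g. complete graphs, come back
// unchanged). Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_swaps,
                               int max_attempts_factor = 100) {
  int m = edges.nrow();
  if (m < 2) stop("rewiring needs at least 2 edges");
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  present.reserve(2 * m);
  long long K = 1LL << 32;
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    if (u == v) stop("self-loop in input edge list");
    if (u > v) std::swap(u, v);
    a[e] = u; b[e] = v;
    present.insert((long long)u * K + v);
  }
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
    // randomly choose which endpoints to exchange
    if (unif_rand() < 0.5) { std::swap(u2, v2); }
    // proposed edges: (u1, v2), (u2, v1)
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
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = a[e]; out(e, 1) = b[e]; }
  out.attr("n_successful_swaps") = done;
  return out;
}
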