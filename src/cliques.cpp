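#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Bron-Kerbosch maximal clique enumeration with pivoting, degeneracy vertex
// ordering at the outermost level, and bitset adjacency (64-vertex blocks).

typedef std::vector<uint64_t> BitSet;

static inline bool bs_get(const BitSet& b, int i) {
  return (b[i >> 6] >> (i & 63)) & 1ULL;
}
static inline void bs_set(BitSet& b, int i) { b[i >> 6] |= 1ULL << (i & 63); }
static inline void bs_clear(BitSet& b, int i) { b[i >> 6] &= ~(1ULL << (i & 63)); }
static inline bool bs_empty(const BitSet& b) {
  for (uint64_t w : b) if (w) return false;
  return true;
}

struct BKState {
  std::vector<BitSet> adj;
  int n, nb;
  int min_size;
  std::vector<std::vector<int>> cliques;
};

static void bk_recurse(BKState& st, BitSet P, BitSet X, std::vector<int>& R) {
  if (bs_empty(P) && bs_empty(X)) {
    if ((int)R.size() >= st.min_size) st.cliques.push_back(R);
    return;
  }
  // pivot u in P|X maximizing |P & N(u)|
  int pivot = -1, bestc = -1;
  for (int v = 0; v < st.n; ++v) {
    if (bs_get(P, v) || bs_get(X, v)) {
      int c = 0;
      for (int b = 0; b < st.nb; ++b)
        c += __builtin_popcountll(P[b] & st.adj[v][b]);
      if (c > bestc) { bestc = c; pivot = v; }
    }
  }
  std::vector<int> cand;
  for (int v = 0; v < st.n; ++v)
    if (bs_get(P, v) && !bs_get(st.adj[pivot], v)) cand.push_back(v);
  for (int v : cand) {
    BitSet P2(st.nb), X2(st.nb);
    for (int b = 0; b < st.nb; ++b) {
      P2[b] = P[b] & st.adj[v][b];
      X2[b] = X[b] & st.adj[v][b];
    }
    R.push_back(v);
    bk_recurse(st, P2, X2, R);
    R.pop_back();
    bs_clear(P, v);
    bs_set(X, v);
  }
}

// edges: 2-column integer matrix of 1-based vertex indices; n vertices.
// Returns a list of integer vectors (1-based, sorted) — the maximal cliques
// with at least min_size members.
//
// [[Rcpp::export]]
List maximal_cliques_cpp(IntegerMatrix edges, int n, int min_size) {
  BKState st;
  st.n = n;
  st.nb = (n + 63) / 64;
  st.min_size = min_size;
  st.adj.assign(n, BitSet(st.nb, 0));
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u == v) continue;
    bs_set(st.adj[u], v);
    bs_set(st.adj[v], u);
  }

  // degeneracy ordering: repeatedly remove a minimum-degree vertex
  std::vector<int> deg(n, 0), order;
  std::vector<bool> removed(n, false);
  for (int v = 0; v < n; ++v)
    for (int b = 0; b < st.nb; ++b)
      deg[v] += __builtin_popcountll(st.adj[v][b]);
  for (int step = 0; step < n; ++step) {
    int best = -1;
    for (int v = 0; v < n; ++v)
      if (!removed[v] && (best < 0 || deg[v] < deg[best])) best = v;
    removed[best] = true;
    order.push_back(best);
    for (int u = 0; u < n; ++u)
      if (!removed[u] && bs_get(st.adj[best], u)) deg[u]--;
  }
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[order[i]] = i;

  BitSet done(st.nb, 0);
  for (int i = 0; i < n; ++i) {
    int v = order[i];
    BitSet P(st.nb, 0), X(st.nb, 0);
    for (int u = 0; u < n; ++u) {
      if (!bs_get(st.adj[v], u)) continue;
      if (pos[u] > i) bs_set(P, u); else bs_set(X, u);
    }
    std::vector<int> R;
    R.push_back(v);
    bk_recurse(st, P, X, R);
  }

  List out(st.cliques.size());
  for (size_t i = 0; i < st.cliques.size(); ++i) {
    std::vector<int> c = st.cliques[i];
    std::sort(c.begin(), c.end());
    IntegerVector iv(c.size());
    for (size_t j = 0; j < c.size(); ++j) iv[j] = c[j] + 1;
    out[i] = iv;
  }
  return out;
}
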