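// Maximal k-plex enumeration and plex-overlap percolation.
//
// The enumerator is a Bron-Kerbosch-style recursive backtracking over
// (R, P, X): R the growing plex, P vertices that may still extend R,
// X vertices that extend R but were already branched on.  Because every
// subset of a k-plex is a k-plex, candidates for R + v are always a
// subset of candidates for R, so the classic BK bookkeeping enumerates
// every inclusion-maximal k-plex exactly once (reported when P and X
// are both empty).  Vertices are pre-peeled (degree < m - k cannot sit
// in a plex of size >= m) and, when m >= 2k - 1 (any k-plex of that
// size is connected), the search runs per connected component.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> Bits;

inline void bit_set(Bits &b, int i) { b[i >> 6] |= (uint64_t(1) << (i & 63)); }
inline bool bit_get(const Bits &b, int i) {
  return (b[i >> 6] >> (i & 63)) & uint64_t(1);
}
// true iff a is a subset of b
inline bool bit_subset(const Bits &a, const Bits &b) {
  for (size_t w = 0; w < a.size(); ++w)
    if (a[w] & ~b[w]) return false;
  return true;
}

struct Enumerator {
  int p, m, k, words;
  std::vector<std::vector<int> > nbr;  // adjacency lists
  std::vector<Bits> adj;               // adjacency bitsets
  std::vector<int> deg_in_R;           // degree within R, all vertices
  std::vector<int> R;
  Bits Rmask;
  std::vector<std::vector<int> > out;

  Enumerator(int p_, int m_, int k_) : p(p_), m(m_), k(k_) {
    words = (p + 63) / 64;
    nbr.assign(p, std::vector<int>());
    adj.assign(p, Bits(words, 0));
    deg_in_R.assign(p, 0);
    Rmask.assign(words, 0);
  }

  void add_edge(int u, int v) {
    nbr[u].push_back(v);
    nbr[v].push_back(u);
    bit_set(adj[u], v);
    bit_set(adj[v], u);
  }

  // can u be added to R keeping the k-plex property?
  // crit = members of R whose slack is exhausted (deg_in_R == |R| - k).
  inline bool addable(int u, const Bits &crit) const {
    if (deg_in_R[u] < (int)R.size() + 1 - k) return false;
    return bit_subset(crit, adj[u]);
  }

  void recurse(std::vector<int> &P, std::vector<int> &X) {
    if (P.empty()) {
      if (X.empty() && (int)R.size() >= m)
        out.push_back(R);
      return;
    }
    if ((int)(R.size() + P.size()) < m) return;

    // dominance prune: an excluded vertex adjacent to everything still
    // reachable extends every leaf of this subtree, so none is maximal
    Bits reach(Rmask);
    for (size_t i = 0; i < P.size(); ++i) bit_set(reach, P[i]);
    for (size_t i = 0; i < X.size(); ++i)
      if (bit_subset(reach, adj[X[i]])) return;

    std::vector<int> Pl(P), Xl(X);
    for (size_t idx = 0; idx < Pl.size(); ++idx) {
      int v = Pl[idx];
      // extend R by v
      R.push_back(v);
      bit_set(Rmask, v);
      for (size_t j = 0; j < nbr[v].size(); ++j) ++deg_in_R[nbr[v][j]];

      Bits crit(words, 0);
      int need = (int)R.size() - k;
      for (size_t j = 0; j < R.size(); ++j)
        if (deg_in_R[R[j]] == need) bit_set(crit, R[j]);

      std::vector<int> P2, X2;
      for (size_t j = idx + 1; j < Pl.size(); ++j)
        if (addable(Pl[j], crit)) P2.push_back(Pl[j]);
      for (size_t j = 0; j < Xl.size(); ++j)
        if (addable(Xl[j], crit)) X2.push_back(Xl[j]);

      recurse(P2, X2);

      // retract v, move it to X
      for (size_t j = 0; j < nbr[v].size(); ++j) --deg_in_R[nbr[v][j]];
      Rmask[v >> 6] &= ~(uint64_t(1) << (v & 63));
      R.pop_back();
      Xl.push_back(v);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".kplex_enum_cpp")]]
List kplex_enum_cpp(int p, IntegerMatrix edges, int m, int k) {
  Enumerator en(p, m, k);
  for (int e = 0; e < edges.nrow(); ++e) en.add_edge(edges(e, 0), edges(e, 1));

  // peel vertices that cannot belong to any k-plex of size >= m
  std::vector<int> deg(p, 0);
  std::vector<bool> alive(p, true);
  for (int v = 0; v < p; ++v) deg[v] = (int)en.nbr[v].size();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int v = 0; v < p; ++v)
      if (alive[v] && deg[v] < m - k) {
        alive[v] = false;
        changed = true;
        for (size_t j = 0; j < en.nbr[v].size(); ++j)
          if (alive[en.nbr[v][j]]) --deg[en.nbr[v][j]];
      }
  }

  if (m >= 2 * k - 1) {
    // size >= m forces connectivity: enumerate per connected component
    std::vector<int> comp(p, -1);
    int nc = 0;
    std::vector<int> stack;
    for (int s = 0; s < p; ++s) {
      if (!alive[s] || comp[s] >= 0) continue;
      comp[s] = nc;
      stack.push_back(s);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        for (size_t j = 0; j < en.nbr[v].size(); ++j) {
          int u = en.nbr[v][j];
          if (alive[u] && comp[u] < 0) {
            comp[u] = nc;
            stack.push_back(u);
          }
        }
      }
      ++nc;
    }
    for (int c = 0; c < nc; ++c) {
      std::vector<int> P, X;
      for (int v = 0; v < p; ++v)
        if (alive[v] && comp[v] == c) P.push_back(v);
      if ((int)P.size() < m) continue;
      en.recurse(P, X);
    }
  } else {
    // disconnected plexes are possible (m < 2k - 1): whole graph at once
    std::vector<int> P, X;
    for (int v = 0; v < p; ++v)
      if (alive[v]) P.push_back(v);
    en.recurse(P, X);
  }

  for (size_t i = 0; i < en.out.size(); ++i)
    std::sort(en.out[i].begin(), en.out[i].end());
  std::sort(en.out.begin(), en.out.end());

  List res(en.out.size());
  for (size_t i = 0; i < en.out.size(); ++i)
    res[i] = IntegerVector(en.out[i].begin(), en.out[i].end());
  return res;
}

// Union-find grouping of vertex sets by pairwise overlap >= threshold.
// The secondary overlap graph is never materialized; an inverted
// vertex -> set index is used to visit only pairs that share a vertex.
// [[Rcpp::export(name = ".overlap_components_cpp")]]
IntegerVector overlap_components_cpp(List sets, int threshold) {
  int n = sets.size();
  std::vector<std::vector<int> > items(n);
  int maxv = -1;
  for (int i = 0; i < n; ++i) {
    IntegerVector s = sets[i];
    items[i].assign(s.begin(), s.end());
    for (size_t j = 0; j < items[i].size(); ++j)
      if (items[i][j] > maxv) maxv = items[i][j];
  }
  std::vector<std::vector<int> > inc(maxv + 1);
  for (int i = 0; i < n; ++i)
    for (size_t j = 0; j < items[i].size(); ++j)
      inc[items[i][j]].push_back(i);

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  struct UF {
    std::vector<int> &par;
    UF(std::vector<int> &p) : par(p) {}
    int find(int x) {
      while (par[x] != x) {
        par[x] = par[par[x]];
        x = par[x];
      }
      return x;
    }
    void unite(int a, int b) {
      a = find(a);
      b = find(b);
      if (a != b) par[a] = b;
    }
  } uf(parent);

  std::vector<int> cnt(n, 0), touched;
  for (int i = 0; i < n; ++i) {
    touched.clear();
    for (size_t j = 0; j < items[i].size(); ++j) {
      const std::vector<int> &lst = inc[items[i][j]];
      for (size_t q = 0; q < lst.size(); ++q) {
        int other = lst[q];
        if (other <= i) continue;
        if (cnt[other] == 0) touched.push_back(other);
        ++cnt[other];
      }
    }
    for (size_t q = 0; q < touched.size(); ++q) {
      if (cnt[touched[q]] >= threshold) uf.unite(i, touched[q]);
      cnt[touched[q]] = 0;
    }
  }

  // canonical 0-based component ids in first-appearance order
  IntegerVector comp(n);
  std::vector<int> label(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (label[r] < 0) label[r] = next++;
    comp[i] = label[r];
  }
  return comp;
}
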