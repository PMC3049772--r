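#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <cstdio>
#include <map>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// Canonical colored-motif keys and the ESU (FANMOD) census.
//
// A motif on k nodes is encoded as (adjacency-code, color-code):
//   adjacency-code: off-diagonal entries a_ij read row-major (i, then j != i),
//     first entry = most significant bit; L = k(k-1) bits.
//   color-code: the k color indices (0-based) read as decimal digits.
// The canonical form is the lexicographic minimum of the pair
// (adjacency-code, color sequence) over all k! simultaneous node
// permutations. Undirected edges are symmetric in the matrix, so the same
// machinery serves both modes; the mode letter in the key string keeps the
// two spaces distinct.

static const int MAXK = 5;

struct Perms {
  std::vector<std::array<int, MAXK> > p;
};

static Perms &perms_for(int k) {
  static Perms cache[MAXK + 1];
  Perms &pk = cache[k];
  if (pk.p.empty()) {
    std::array<int, MAXK> idx;
    for (int i = 0; i < k; ++i) idx[i] = i;
    do {
      pk.p.push_back(idx);
    } while (std::next_permutation(idx.begin(), idx.begin() + k));
  }
  return pk;
}

// canonical (adjcode, colorcode) over all permutations; colorcode is the
// decimal-digit packing of the permuted color sequence
static void canonical_pair(int k, const int adj[MAXK][MAXK], const int *colors,
                           uint64_t &best_code, uint64_t &best_col) {
  Perms &pk = perms_for(k);
  bool first = true;
  for (size_t t = 0; t < pk.p.size(); ++t) {
    const std::array<int, MAXK> &p = pk.p[t];
    uint64_t code = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (i != j) code = (code << 1) | (uint64_t)adj[p[i]][p[j]];
    uint64_t col = 0;
    for (int i = 0; i < k; ++i) col = col * 10 + (uint64_t)colors[p[i]];
    if (first || code < best_code || (code == best_code && col < best_col)) {
      best_code = code;
      best_col = col;
      first = false;
    }
  }
}

static bool weakly_connected(int k, const int adj[MAXK][MAXK]) {
  bool seen[MAXK] = {false};
  int stack[MAXK], top = 0;
  stack[top++] = 0;
  seen[0] = true;
  int cnt = 1;
  while (top > 0) {
    int v = stack[--top];
    for (int u = 0; u < k; ++u)
      if (!seen[u] && (adj[v][u] || adj[u][v])) {
        seen[u] = true;
        stack[top++] = u;
        ++cnt;
      }
  }
  return cnt == k;
}

static std::string key_string(int k, bool directed, uint64_t code,
                              uint64_t col) {
  char buf[64];
  // color digits padded to width k so the key is unambiguous
  char colbuf[8];
  for (int i = k - 1; i >= 0; --i) {
    colbuf[i] = '0' + (int)(col % 10);
    col /= 10;
  }
  colbuf[k] = '\0';
  snprintf(buf, sizeof(buf), "%d|%c|%llu|%s", k, directed ? 'd' : 'u',
           (unsigned long long)code, colbuf);
  return std::string(buf);
}

// [[Rcpp::export]]
String cpp_canonical_key(IntegerMatrix adj, IntegerVector colors,
                         bool directed) {
  int k = adj.nrow();
  if (k < 2 || k > MAXK) stop("motif size must be between 2 and 5");
  if (adj.ncol() != k) stop("adjacency matrix must be square");
  if ((int)colors.size() != k) stop("need one color per node");
  int a[MAXK][MAXK] = {{0}};
  int col[MAXK];
  for (int i = 0; i < k; ++i) {
    col[i] = colors[i];
    if (col[i] < 0 || col[i] > 9) stop("color indices must be in 0..9");
    for (int j = 0; j < k; ++j) {
      if (i == j) {
        if (adj(i, j) != 0) stop("self-loops are not allowed");
        continue;
      }
      a[i][j] = adj(i, j) != 0 ? 1 : 0;
    }
  }
  if (!directed)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (a[i][j] != a[j][i]) stop("undirected adjacency must be symmetric");
  if (!weakly_connected(k, a)) stop("subgraph is not connected");
  uint64_t code, ccol;
  canonical_pair(k, a, col, code, ccol);
  return key_string(k, directed, code, ccol);
}

// ---------------------------------------------------------------------------
// ESU enumeration

struct Esu {
  int n, k;
  bool directed, collect;
  std::vector<std::vector<int> > nbr;     // symmetrized adjacency lists
  std::vector<std::vector<unsigned char> > adj;  // mode adjacency
  const int *colors;
  std::map<std::pair<uint64_t, uint64_t>, double> counts;
  std::vector<int> sub;
  std::vector<char> in_nbh;  // node in sub or adjacent to sub
  std::vector<std::vector<int> > subsets;

  void record() {
    if (collect) {
      subsets.push_back(sub);
      return;
    }
    int a[MAXK][MAXK] = {{0}};
    int col[MAXK];
    for (int i = 0; i < k; ++i) {
      col[i] = colors[sub[i]];
      for (int j = 0; j < k; ++j)
        if (i != j) a[i][j] = adj[sub[i]][sub[j]];
    }
    uint64_t code, ccol;
    canonical_pair(k, a, col, code, ccol);
    counts[std::make_pair(code, ccol)] += 1.0;
  }

  void extend(std::vector<int> &ext, int v) {
    if ((int)sub.size() == k) {
      record();
      return;
    }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> newly;
      for (size_t t = 0; t < nbr[w].size(); ++t) {
        int u = nbr[w][t];
        if (u > v && !in_nbh[u]) {
          ext2.push_back(u);
          newly.push_back(u);
          in_nbh[u] = 1;
        }
      }
      sub.push_back(w);
      extend(ext2, v);
      sub.pop_back();
      for (size_t t = 0; t < newly.size(); ++t) in_nbh[newly[t]] = 0;
    }
  }

  void run() {
    in_nbh.assign(n, 0);
    for (int v = 0; v < n; ++v) {
      sub.clear();
      sub.push_back(v);
      in_nbh[v] = 1;
      std::vector<int> ext;
      for (size_t t = 0; t < nbr[v].size(); ++t) {
        int u = nbr[v][t];
        if (u > v) {
          ext.push_back(u);
          in_nbh[u] = 1;
        }
      }
      std::vector<int> marked = ext;
      extend(ext, v);
      in_nbh[v] = 0;
      for (size_t t = 0; t < marked.size(); ++t) in_nbh[marked[t]] = 0;
    }
  }
};

static void build_graph(Esu &e, int n, IntegerMatrix edges, bool directed) {
  e.n = n;
  e.directed = directed;
  e.adj.assign(n, std::vector<unsigned char>(n, 0));
  for (int r = 0; r < edges.nrow(); ++r) {
    int u = edges(r, 0) - 1, v = edges(r, 1) - 1;
    if (u < 0 || u >= n || v < 0 || v >= n) stop("edge endpoint out of range");
    if (u == v) stop("self-loops are not allowed");
    e.adj[u][v] = 1;
    if (!directed) e.adj[v][u] = 1;
  }
  e.nbr.assign(n, std::vector<int>());
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      if (v != u && (e.adj[u][v] || e.adj[v][u])) e.nbr[u].push_back(v);
}

// Census of induced connected k-subgraphs by canonical colored class.
// edges: 1-based (from, to) pairs; arcs for directed mode (links already
// expanded), one row per link for undirected mode. colors: 0-based indices.
// [[Rcpp::export]]
NumericVector cpp_motif_census(int n, IntegerMatrix edges,
                               IntegerVector colors, int k, bool directed) {
  if (k < 2 || k > MAXK) stop("motif size must be between 2 and 5");
  if ((int)colors.size() != n) stop("need one color per node");
  Esu e;
  build_graph(e, n, edges, directed);
  e.k = k;
  e.collect = false;
  std::vector<int> cols(colors.begin(), colors.end());
  for (int i = 0; i < n; ++i)
    if (cols[i] < 0 || cols[i] > 9) stop("color indices must be in 0..9");
  e.colors = cols.data();
  if (k <= n) e.run();
  NumericVector out(e.counts.size());
  CharacterVector nm(e.counts.size());
  int i = 0;
  for (std::map<std::pair<uint64_t, uint64_t>, double>::iterator it =
           e.counts.begin();
       it != e.counts.end(); ++it, ++i) {
    out[i] = it->second;
    nm[i] = key_string(k, directed, it->first.first, it->first.second);
  }
  out.names() = nm;
  return out;
}

// All connected induced k-subsets (1-based node indices, one row each).
// [[Rcpp::export]]
IntegerMatrix cpp_connected_subsets(int n, IntegerMatrix edges, int k,
                                    bool directed) {
  if (k < 2 || k > MAXK) stop("motif size must be between 2 and 5");
  Esu e;
  build_graph(e, n, edges, directed);
  e.k = k;
  e.collect = true;
  static int dummy_colors[1] = {0};
  e.colors = dummy_colors;
  if (k <= n) e.run();
  IntegerMatrix out(e.subsets.size(), k);
  for (size_t r = 0; r < e.subsets.size(); ++r) {
    std::vector<int> s = e.subsets[r];
    std::sort(s.begin(), s.end());
    for (int j = 0; j < k; ++j) out(r, j) = s[j] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force enumeration of all possible connected colored motif classes

// [[Rcpp::export]]
CharacterVector cpp_enumerate_classes(int k, int n_colors, bool directed) {
  if (k < 2 || k > 4) stop("class enumeration supports sizes 2 to 4 only");
  if (n_colors < 1 || n_colors > 9) stop("n_colors must be in 1..9");
  // off-diagonal positions in row-major order (the code bit order)
  std::vector<std::pair<int, int> > pos;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) pos.push_back(std::make_pair(i, j));
  int L = (int)pos.size();
  std::vector<std::pair<int, int> > upos;  // i<j pairs for undirected
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) upos.push_back(std::make_pair(i, j));
  int nbits = directed ? L : (int)upos.size();
  long ncolorings = 1;
  for (int i = 0; i < k; ++i) ncolorings *= n_colors;

  std::set<std::pair<uint64_t, uint64_t> > classes;
  for (long mask = 0; mask < (1L << nbits); ++mask) {
    int a[MAXK][MAXK] = {{0}};
    if (directed) {
      for (int b = 0; b < nbits; ++b)
        if (mask & (1L << b)) a[pos[b].first][pos[b].second] = 1;
    } else {
      for (int b = 0; b < nbits; ++b)
        if (mask & (1L << b)) {
          a[upos[b].first][upos[b].second] = 1;
          a[upos[b].second][upos[b].first] = 1;
        }
    }
    if (!weakly_connected(k, a)) continue;
    for (long c = 0; c < ncolorings; ++c) {
      int col[MAXK];
      long cc = c;
      for (int i = k - 1; i >= 0; --i) {
        col[i] = (int)(cc % n_colors);
        cc /= n_colors;
      }
      uint64_t code, ccol;
      canonical_pair(k, a, col, code, ccol);
      classes.insert(std::make_pair(code, ccol));
    }
  }
  CharacterVector out(classes.size());
  int i = 0;
  for (std::set<std::pair<uint64_t, uint64_t> >::iterator it = classes.begin();
       it != classes.end(); ++it, ++i)
    out[i] = key_string(k, directed, it->first, it->second);
  return out;
}
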