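#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Unweighted, undirected simple graphs passed as 0/1 adjacency matrices.
// All kernels treat any nonzero entry as an edge and ignore the diagonal.
// Hot paths (efficiencies, rewiring) run on row bitmasks.

static std::vector<std::vector<int> > adjacency_lists(const IntegerMatrix& A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

static std::vector<uint64_t> row_masks(const IntegerMatrix& A, int words) {
  const int n = A.nrow();
  std::vector<uint64_t> rows((size_t) n * words, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && A(i, j) != 0)
        rows[(size_t) i * words + j / 64] |= (uint64_t) 1 << (j % 64);
  return rows;
}

// BFS from a single source over adjacency lists; dist -1 when unreachable.
static void bfs(const std::vector<std::vector<int> >& adj, int s,
                std::vector<int>& dist, std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  int head = 0, tail = 0;
  dist[s] = 0;
  queue[tail++] = s;
  while (head < tail) {
    int u = queue[head++];
    const std::vector<int>& nb = adj[u];
    for (size_t k = 0; k < nb.size(); ++k) {
      int v = nb[k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; queue[tail++] = v; }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix bfs_distance_matrix_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > adj = adjacency_lists(A);
  std::vector<int> dist(n), queue(n);
  NumericMatrix D(n, n);
  for (int s = 0; s < n; ++s) {
    bfs(adj, s, dist, queue);
    for (int v = 0; v < n; ++v)
      D(s, v) = dist[v] < 0 ? R_PosInf : (double) dist[v];
  }
  return D;
}

// Bitset BFS over row masks (stride = words); returns sum of 1/d over all
// nodes reachable from s.
static double bitset_bfs_invdist(const uint64_t* rows, int words, int s,
                                 uint64_t* visited, uint64_t* frontier,
                                 uint64_t* next) {
  for (int w = 0; w < words; ++w) { visited[w] = 0; frontier[w] = 0; }
  visited[s >> 6] |= (uint64_t) 1 << (s & 63);
  frontier[s >> 6] |= (uint64_t) 1 << (s & 63);
  double acc = 0.0;
  int d = 0;
  bool any = true;
  while (any) {
    ++d;
    for (int w = 0; w < words; ++w) next[w] = 0;
    for (int w = 0; w < words; ++w) {
      uint64_t f = frontier[w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* row = rows + (size_t) (w * 64 + b) * words;
        for (int w2 = 0; w2 < words; ++w2) next[w2] |= row[w2];
      }
    }
    any = false;
    int cnt = 0;
    for (int w = 0; w < words; ++w) {
      next[w] &= ~visited[w];
      visited[w] |= next[w];
      if (next[w]) { any = true; cnt += __builtin_popcountll(next[w]); }
      frontier[w] = next[w];
    }
    if (cnt) acc += (double) cnt / d;
  }
  return acc;
}

// E_glob from row masks: mean over ordered pairs of 1/L_ij.
static double global_efficiency_masks(const std::vector<uint64_t>& rows,
                                      int n, int words) {
  if (n < 2) return 0.0;
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  double total = 0.0;
  for (int s = 0; s < n; ++s)
    total += bitset_bfs_invdist(rows.data(), words, s,
                                visited.data(), frontier.data(), next.data());
  return total / ((double) n * (n - 1));
}

// E_loc from row masks: mean over nodes of E_glob of the neighbour-induced
// subgraph (index node excluded; < 2 neighbours contributes 0).
static double local_efficiency_masks(const std::vector<uint64_t>& rows,
                                     int n, int words) {
  if (n == 0) return 0.0;
  std::vector<int> nb(n), wv(n);
  std::vector<uint64_t> mv(n);
  std::vector<uint64_t> sub((size_t) n * words);
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    const uint64_t* ri = &rows[(size_t) i * words];
    for (int w = 0; w < words; ++w) {
      uint64_t f = ri[w];
      while (f) { int b = __builtin_ctzll(f); f &= f - 1; nb[k++] = w * 64 + b; }
    }
    if (k < 2) continue;
    const int wk = (k + 63) / 64;
    for (int v = 0; v < k; ++v) {
      wv[v] = nb[v] >> 6;
      mv[v] = (uint64_t) 1 << (nb[v] & 63);
    }
    double acc = 0.0;
    if (wk == 1) {
      // single-word subgraph (k <= 64): unrolled bitset BFS
      for (int u = 0; u < k; ++u) {
        const uint64_t* ru = &rows[(size_t) nb[u] * words];
        uint64_t m = 0;
        for (int v = 0; v < k; ++v)
          if (v != u && (ru[wv[v]] & mv[v])) m |= (uint64_t) 1 << v;
        sub[u] = m;
      }
      for (int s = 0; s < k; ++s) {
        uint64_t vis = (uint64_t) 1 << s;
        uint64_t frontier = vis;
        int d = 0;
        while (frontier) {
          ++d;
          uint64_t nxt = 0, f = frontier;
          while (f) { nxt |= sub[__builtin_ctzll(f)]; f &= f - 1; }
          frontier = nxt & ~vis;
          vis |= frontier;
          if (frontier) acc += (double) __builtin_popcountll(frontier) / d;
        }
      }
    } else {
      for (int u = 0; u < k; ++u) {
        const uint64_t* ru = &rows[(size_t) nb[u] * words];
        uint64_t* su = &sub[(size_t) u * wk];
        for (int w = 0; w < wk; ++w) su[w] = 0;
        for (int v = 0; v < k; ++v)
          if (v != u && (ru[wv[v]] & mv[v]))
            su[v >> 6] |= (uint64_t) 1 << (v & 63);
      }
      for (int s = 0; s < k; ++s)
        acc += bitset_bfs_invdist(sub.data(), wk, s,
                                  visited.data(), frontier.data(), next.data());
    }
    total += acc / ((double) k * (k - 1));
  }
  return total / n;
}

// [[Rcpp::export]]
NumericVector nodal_efficiency_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  NumericVector e(n);
  if (n < 2) return e;
  const int words = (n + 63) / 64;
  std::vector<uint64_t> rows = row_masks(A, words);
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  for (int s = 0; s < n; ++s)
    e[s] = bitset_bfs_invdist(rows.data(), words, s, visited.data(),
                              frontier.data(), next.data()) / (n - 1);
  return e;
}

// [[Rcpp::export]]
double global_efficiency_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  const int words = (n + 63) / 64;
  return global_efficiency_masks(row_masks(A, words), n, words);
}

// [[Rcpp::export]]
double local_efficiency_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  const int words = (n + 63) / 64;
  return local_efficiency_masks(row_masks(A, words), n, words);
}

// Brandes accumulation; returns betweenness over unordered pairs.
// [[Rcpp::export]]
NumericVector betweenness_cpp(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > adj = adjacency_lists(A);
  NumericVector bc(n);
  std::vector<int> dist(n), queue(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    int head = 0, tail = 0;
    dist[s] = 0; sigma[s] = 1.0; queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      const std::vector<int>& nb = adj[u];
      for (size_t k = 0; k < nb.size(); ++k) {
        int v = nb[k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue[tail++] = v; }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    for (int idx = tail - 1; idx >= 0; --idx) {
      int w = queue[idx];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // each unordered pair visited twice
  return bc;
}

// Double-edge-swap kernel shared by rewire_adjacency_cpp and
// null_ensemble_cpp so both give identical graphs for identical RNG state.
// Each attempt draws two edges; the orientation coin reuses the fractional
// part of the first draw. Returns the number of rejected attempts.
static long do_swaps(std::vector<uint64_t>& bits, std::vector<int>& ea,
                     std::vector<int>& eb, int words, int n_swaps) {
  const int m = (int) ea.size();
  long skipped = 0;
  if (m < 2) return n_swaps;
  for (int t = 0; t < n_swaps; ++t) {
    double u1 = unif_rand() * m;
    int e1 = (int) u1; if (e1 == m) e1 = m - 1;
    int e2 = (int) (unif_rand() * m); if (e2 == m) e2 = m - 1;
    if (e1 == e2) { ++skipped; continue; }
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (u1 - e1 < 0.5) { int tmp = c; c = d; d = tmp; }
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b || a == c || b == d) { ++skipped; continue; }
    if ((bits[(size_t) a * words + (d >> 6)] >> (d & 63) & 1) ||
        (bits[(size_t) c * words + (b >> 6)] >> (b & 63) & 1)) { ++skipped; continue; }
    bits[(size_t) a * words + (b >> 6)] &= ~((uint64_t) 1 << (b & 63));
    bits[(size_t) b * words + (a >> 6)] &= ~((uint64_t) 1 << (a & 63));
    bits[(size_t) c * words + (d >> 6)] &= ~((uint64_t) 1 << (d & 63));
    bits[(size_t) d * words + (c >> 6)] &= ~((uint64_t) 1 << (c & 63));
    bits[(size_t) a * words + (d >> 6)] |= (uint64_t) 1 << (d & 63);
    bits[(size_t) d * words + (a >> 6)] |= (uint64_t) 1 << (a & 63);
    bits[(size_t) c * words + (b >> 6)] |= (uint64_t) 1 << (b & 63);
    bits[(size_t) b * words + (c >> 6)] |= (uint64_t) 1 << (c & 63);
    ea[e1] = a < d ? a : d; eb[e1] = a < d ? d : a;
    ea[e2] = c < b ? c : b; eb[e2] = c < b ? b : c;
  }
  return skipped;
}

static void edges_from_masks(const std::vector<uint64_t>& bits, int n,
                             int words, std::vector<int>& ea,
                             std::vector<int>& eb) {
  ea.clear(); eb.clear();
  for (int i = 0; i < n; ++i)
    for (int w = 0; w < words; ++w) {
      uint64_t f = bits[(size_t) i * words + w];
      while (f) {
        int b = __builtin_ctzll(f);
        f &= f - 1;
        int j = w * 64 + b;
        if (j > i) { ea.push_back(i); eb.push_back(j); }
      }
    }
}

// Degree-preserving double-edge swaps (Markov-chain rewiring). Draws come
// from R's RNG so set.seed() makes runs bit-reproducible. Attribute
// "skipped" counts rejected attempts.
// [[Rcpp::export]]
IntegerMatrix rewire_adjacency_cpp(IntegerMatrix A, int n_swaps) {
  const int n = A.nrow();
  const int words = (n + 63) / 64;
  std::vector<uint64_t> bits = row_masks(A, words);
  std::vector<int> ea, eb;
  edges_from_masks(bits, n, words, ea, eb);
  long skipped = do_swaps(bits, ea, eb, words, n_swaps);
  IntegerMatrix out(n, n);
  for (size_t e = 0; e < ea.size(); ++e) {
    out(ea[e], eb[e]) = 1;
    out(eb[e], ea[e]) = 1;
  }
  out.attr("skipped") = (double) skipped;
  return out;
}

// Whole null ensemble in one call: for each seed, reseed R's RNG, rewire a
// fresh copy of the network with swap_factor * E attempted swaps, and
// record global and local efficiency of the rewired graph.
// [[Rcpp::export]]
List null_ensemble_cpp(IntegerMatrix A, IntegerVector seeds, int swap_factor) {
  const int n = A.nrow();
  const int words = (n + 63) / 64;
  const std::vector<uint64_t> bits0 = row_masks(A, words);
  std::vector<int> ea0, eb0;
  edges_from_masks(bits0, n, words, ea0, eb0);
  const int m = (int) ea0.size();
  const int n_random = seeds.size();
  NumericVector eg(n_random), el(n_random);
  Function set_seed("set.seed");
  std::vector<uint64_t> bits;
  std::vector<int> ea, eb;
  for (int r = 0; r < n_random; ++r) {
    PutRNGstate();
    set_seed(seeds[r]);
    GetRNGstate();
    bits = bits0; ea = ea0; eb = eb0;
    do_swaps(bits, ea, eb, words, swap_factor * m);
    eg[r] = global_efficiency_masks(bits, n, words);
    el[r] = local_efficiency_masks(bits, n, words);
  }
  return List::create(Named("e_glob") = eg, Named("e_loc") = el);
}

// Nodal efficiency of a single node (sum of inverse distances from it);
// cheap path for generators that only track one designated region.
// [[Rcpp::export]]
double nodal_efficiency_single_cpp(IntegerMatrix A, int node) {
  const int n = A.nrow();
  if (n < 2) return 0.0;
  const int words = (n + 63) / 64;
  std::vector<uint64_t> rows = row_masks(A, words);
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  return bitset_bfs_invdist(rows.data(), words, node, visited.data(),
                            frontier.data(), next.data()) / (n - 1);
}
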