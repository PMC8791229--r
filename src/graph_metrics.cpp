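// Binary-graph topology kernels used by the R wrappers in R/metrics.R.
// Graphs are undirected, simple, with zero diagonal; adjacency rows are
// stored as 64-bit bitsets so BFS frontiers expand by word-wise OR.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

typedef uint64_t word;

static inline int popcnt(word x) { return __builtin_popcountll(x); }

struct BitGraph {
  int n, W;
  std::vector<word> adj;  // row-major, n * W words
  word* row(int i) { return adj.data() + (size_t)i * W; }
  const word* row(int i) const { return adj.data() + (size_t)i * W; }
  bool has(int i, int j) const { return (row(i)[j >> 6] >> (j & 63)) & 1ull; }
  void set_edge(int i, int j) {
    row(i)[j >> 6] |= (word(1) << (j & 63));
    row(j)[i >> 6] |= (word(1) << (i & 63));
  }
  void clear_edge(int i, int j) {
    row(i)[j >> 6] &= ~(word(1) << (j & 63));
    row(j)[i >> 6] &= ~(word(1) << (i & 63));
  }
  int degree(int i) const {
    int d = 0;
    for (int w = 0; w < W; ++w) d += popcnt(row(i)[w]);
    return d;
  }
};

static BitGraph make_graph(const IntegerMatrix& A) {
  int n = A.nrow();
  BitGraph g;
  g.n = n;
  g.W = (n + 63) / 64;
  g.adj.assign((size_t)n * g.W, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) g.set_edge(i, j);
  return g;
}

static IntegerMatrix to_matrix(const BitGraph& g) {
  IntegerMatrix A(g.n, g.n);
  for (int i = 0; i < g.n; ++i)
    for (int j = 0; j < g.n; ++j)
      A(i, j) = (i != j && g.has(i, j)) ? 1 : 0;
  return A;
}

// Per-node clustering coefficient: 2 * (edges among neighbours) / (k (k-1)).
static void clustering_vec(const BitGraph& g, std::vector<double>& c) {
  int n = g.n, W = g.W;
  c.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int k = g.degree(i);
    if (k < 2) continue;
    // sum over neighbours u of |N(u) & N(i)| counts each triangle edge twice
    double t = 0;
    const word* ri = g.row(i);
    for (int w = 0; w < W; ++w) {
      word x = ri[w];
      while (x) {
        int u = (w << 6) + __builtin_ctzll(x);
        x &= x - 1;
        const word* ru = g.row(u);
        int s = 0;
        for (int v = 0; v < W; ++v) s += popcnt(ru[v] & ri[v]);
        t += s;
      }
    }
    c[i] = t / ((double)k * (k - 1));
  }
}

struct PathStats {
  double lp;          // mean distance over connected ordered pairs (NaN if none)
  double eglob;       // mean 1/d over all ordered pairs (1/inf = 0)
  std::vector<double> enod;
  long long unreached_pairs;  // ordered pairs i != j with no path
};

// All-sources BFS using bitset frontiers.
static PathStats path_stats(const BitGraph& g) {
  int n = g.n, W = g.W;
  PathStats out;
  out.enod.assign(n, 0.0);
  double dist_sum = 0, inv_total = 0;
  long long reached_total = 0;
  std::vector<word> visited(W), frontier_mask(W), next_mask(W);
  std::vector<int> frontier;
  frontier.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(visited.begin(), visited.end(), 0);
    visited[s >> 6] |= word(1) << (s & 63);
    frontier.clear();
    frontier.push_back(s);
    double inv = 0;
    long long reached = 0;
    int d = 0;
    while (!frontier.empty() && reached < n - 1) {
      std::fill(next_mask.begin(), next_mask.end(), 0);
      for (int u : frontier) {
        const word* ru = g.row(u);
        for (int w = 0; w < W; ++w) next_mask[w] |= ru[w];
      }
      for (int w = 0; w < W; ++w) next_mask[w] &= ~visited[w];
      ++d;
      frontier.clear();
      int cnt = 0;
      for (int w = 0; w < W; ++w) {
        word x = next_mask[w];
        cnt += popcnt(x);
        visited[w] |= x;
        while (x) {
          frontier.push_back((w << 6) + __builtin_ctzll(x));
          x &= x - 1;
        }
      }
      if (cnt == 0) break;
      inv += (double)cnt / d;
      dist_sum += (double)cnt * d;
      reached += cnt;
    }
    out.enod[s] = (n > 1) ? inv / (n - 1) : 0.0;
    inv_total += inv;
    reached_total += reached;
  }
  long long all_pairs = (long long)n * (n - 1);
  out.eglob = all_pairs > 0 ? inv_total / all_pairs : 0.0;
  out.lp = reached_total > 0 ? dist_sum / reached_total
                             : std::numeric_limits<double>::quiet_NaN();
  out.unreached_pairs = all_pairs - reached_total;
  return out;
}

// Local efficiency of node i: global efficiency of the subgraph induced by
// its neighbours (i removed); 0 for degree < 2.
static void local_eff_vec(const BitGraph& g, std::vector<double>& e) {
  int n = g.n, W = g.W;
  e.assign(n, 0.0);
  std::vector<word> visited(W), next_mask(W);
  std::vector<int> nbr;
  std::vector<const word*> subrow(n, nullptr);
  std::vector<word> submasks;
  for (int i = 0; i < n; ++i) {
    int k = g.degree(i);
    if (k < 2) continue;
    const word* ri = g.row(i);
    nbr.clear();
    for (int w = 0; w < W; ++w) {
      word x = ri[w];
      while (x) {
        nbr.push_back((w << 6) + __builtin_ctzll(x));
        x &= x - 1;
      }
    }
    submasks.assign((size_t)k * W, 0);
    for (int a = 0; a < k; ++a) {
      const word* ru = g.row(nbr[a]);
      word* m = submasks.data() + (size_t)a * W;
      for (int w = 0; w < W; ++w) m[w] = ru[w] & ri[w];
      subrow[nbr[a]] = m;
    }
    double inv_total = 0;
    std::vector<int> frontier;
    for (int a = 0; a < k; ++a) {
      int s = nbr[a];
      std::fill(visited.begin(), visited.end(), 0);
      visited[s >> 6] |= word(1) << (s & 63);
      frontier.clear();
      frontier.push_back(s);
      int d = 0;
      int reached = 0;
      while (!frontier.empty() && reached < k - 1) {
        std::fill(next_mask.begin(), next_mask.end(), 0);
        for (int u : frontier) {
          const word* ru = subrow[u];
          for (int w = 0; w < W; ++w) next_mask[w] |= ru[w];
        }
        for (int w = 0; w < W; ++w) next_mask[w] &= ~visited[w];
        ++d;
        frontier.clear();
        int cnt = 0;
        for (int w = 0; w < W; ++w) {
          word x = next_mask[w];
          cnt += popcnt(x);
          visited[w] |= x;
          while (x) {
            frontier.push_back((w << 6) + __builtin_ctzll(x));
            x &= x - 1;
          }
        }
        if (cnt == 0) break;
        reached += cnt;
        inv_total += (double)cnt / d;
      }
    }
    e[i] = inv_total / ((double)k * (k - 1));
  }
}

static std::vector<std::pair<int, int>> edge_list(const BitGraph& g) {
  std::vector<std::pair<int, int>> ed;
  for (int i = 0; i < g.n; ++i)
    for (int j = i + 1; j < g.n; ++j)
      if (g.has(i, j)) ed.push_back({i, j});
  return ed;
}

// Maslov-Sneppen pairwise edge swaps; rejects self-loops and multi-edges.
// Returns the number of successful swaps.
static long long rewire_core(BitGraph& g, std::vector<std::pair<int, int>>& ed,
                             long long attempts, std::mt19937& rng) {
  long long succ = 0;
  int m = (int)ed.size();
  if (m < 2) return 0;
  for (long long t = 0; t < attempts; ++t) {
    int e1 = (int)(rng() % (uint32_t)m);
    int e2 = (int)(rng() % (uint32_t)m);
    if (e1 == e2) continue;
    int a = ed[e1].first, b = ed[e1].second;
    int c = ed[e2].first, d = ed[e2].second;
    if (rng() & 1u) std::swap(c, d);
    // proposed swap: (a,b),(c,d) -> (a,d),(c,b); need 4 distinct vertices
    if (a == c || a == d || b == c || b == d) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.clear_edge(a, b);
    g.clear_edge(c, d);
    g.set_edge(a, d);
    g.set_edge(c, b);
    ed[e1] = {std::min(a, d), std::max(a, d)};
    ed[e2] = {std::min(c, b), std::max(c, b)};
    ++succ;
  }
  return succ;
}

// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
  BitGraph g = make_graph(A);
  std::vector<double> c;
  clustering_vec(g, c);
  return wrap(c);
}

// [[Rcpp::export]]
List cpp_path_metrics(IntegerMatrix A) {
  BitGraph g = make_graph(A);
  PathStats ps = path_stats(g);
  double lp = std::isnan(ps.lp) ? NA_REAL : ps.lp;
  return List::create(_["lp"] = lp, _["eglob"] = ps.eglob,
                      _["enod"] = wrap(ps.enod),
                      _["unreached_pairs"] = (double)ps.unreached_pairs);
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix A) {
  BitGraph g = make_graph(A);
  std::vector<double> e;
  local_eff_vec(g, e);
  return wrap(e);
}

// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(IntegerMatrix A) {
  // -1 marks unreachable pairs
  BitGraph g = make_graph(A);
  int n = g.n, W = g.W;
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<word> visited(W), next_mask(W);
  std::vector<int> frontier;
  for (int s = 0; s < n; ++s) {
    std::fill(visited.begin(), visited.end(), 0);
    visited[s >> 6] |= word(1) << (s & 63);
    D(s, s) = 0;
    frontier.clear();
    frontier.push_back(s);
    int d = 0;
    while (!frontier.empty()) {
      std::fill(next_mask.begin(), next_mask.end(), 0);
      for (int u : frontier) {
        const word* ru = g.row(u);
        for (int w = 0; w < W; ++w) next_mask[w] |= ru[w];
      }
      for (int w = 0; w < W; ++w) next_mask[w] &= ~visited[w];
      ++d;
      frontier.clear();
      for (int w = 0; w < W; ++w) {
        word x = next_mask[w];
        visited[w] |= x;
        while (x) {
          int v = (w << 6) + __builtin_ctzll(x);
          D(s, v) = d;
          frontier.push_back(v);
          x &= x - 1;
        }
      }
    }
  }
  return D;
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix A, double swaps_per_edge, int seed) {
  BitGraph g = make_graph(A);
  std::vector<std::pair<int, int>> ed = edge_list(g);
  std::mt19937 rng((uint32_t)seed);
  long long attempts = (long long)std::llround(swaps_per_edge * (double)ed.size());
  long long succ = rewire_core(g, ed, attempts, rng);
  return List::create(_["adjacency"] = to_matrix(g), _["n_swaps"] = (double)succ);
}

// Cp and Lp of n_random degree-preserving rewirings of A (one RNG stream).
// [[Rcpp::export]]
NumericMatrix cpp_null_metrics(IntegerMatrix A, int n_random,
                               double swaps_per_edge, int seed) {
  BitGraph g0 = make_graph(A);
  std::vector<std::pair<int, int>> ed0 = edge_list(g0);
  std::mt19937 rng((uint32_t)seed);
  long long attempts = (long long)std::llround(swaps_per_edge * (double)ed0.size());
  NumericMatrix out(n_random, 2);
  colnames(out) = CharacterVector::create("cp", "lp");
  std::vector<double> c;
  for (int r = 0; r < n_random; ++r) {
    BitGraph g = g0;
    std::vector<std::pair<int, int>> ed = ed0;
    rewire_core(g, ed, attempts, rng);
    clustering_vec(g, c);
    double cp = 0;
    for (double x : c) cp += x;
    cp /= g.n;
    PathStats ps = path_stats(g);
    out(r, 0) = cp;
    out(r, 1) = std::isnan(ps.lp) ? NA_REAL : ps.lp;
  }
  return out;
}
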