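#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Small deterministic PRNG machinery. One independent stream is derived per
// start node from (seed, node id), so corpora are reproducible regardless of
// the order in which start nodes are processed.

static inline uint64_t splitmix64_next(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xorshift128p {
  uint64_t s0, s1;
  Xorshift128p(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix64_next(x);
    s1 = splitmix64_next(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // bounded draw; modulo bias is negligible for graph degrees
  inline uint32_t bounded(uint32_t n) { return (uint32_t)(next() % n); }
};

// Generate edge-label-aware random walks over an undirected view of a
// directed labeled edge list.
//
// src, dst, lab: 0-based edge arrays; starts: 0-based start nodes;
// walks_per_node walks of `steps` edge traversals each are generated per
// start. Tokens are encoded in one id space: node i -> i, edge label j ->
// n_nodes + j. A walk from an isolated start node is the single-token
// sentence [start]; otherwise every visited node has at least one neighbor
// (the one the walk came from), so sentences have exactly 2*steps+1 tokens.
// [[Rcpp::export]]
List cpp_generate_walks(int n_nodes, IntegerVector src, IntegerVector dst,
                        IntegerVector lab, IntegerVector starts,
                        int walks_per_node, int steps, double seed) {
  const int n_edges = src.size();
  // degree count over the undirected view; self-loops contribute one slot
  std::vector<int> deg(n_nodes, 0);
  for (int e = 0; e < n_edges; ++e) {
    deg[src[e]]++;
    if (dst[e] != src[e]) deg[dst[e]]++;
  }
  std::vector<int> offs(n_nodes + 1, 0);
  for (int v = 0; v < n_nodes; ++v) offs[v + 1] = offs[v] + deg[v];
  std::vector<int> nbr(offs[n_nodes]), elab(offs[n_nodes]);
  std::vector<int> fill(n_nodes, 0);
  for (int e = 0; e < n_edges; ++e) {
    int s = src[e], d = dst[e], l = lab[e];
    int p = offs[s] + fill[s]++;
    nbr[p] = d; elab[p] = l;
    if (d != s) {
      int q = offs[d] + fill[d]++;
      nbr[q] = s; elab[q] = l;
    }
  }

  const uint64_t base = (uint64_t)(int64_t)seed;
  List out(starts.size() * (R_xlen_t)walks_per_node);
  R_xlen_t k = 0;
  for (int si = 0; si < starts.size(); ++si) {
    const int start = starts[si];
    Xorshift128p rng(base * 0x9E3779B97F4A7C15ULL ^
                     ((uint64_t)(start + 1) * 0xD1B54A32D192ED03ULL));
    for (int w = 0; w < walks_per_node; ++w) {
      if (deg[start] == 0) {
        out[k++] = IntegerVector::create(start);
        continue;
      }
      IntegerVector sent(2 * steps + 1);
      int cur = start;
      sent[0] = cur;
      for (int t = 0; t < steps; ++t) {
        int pick = offs[cur] + rng.bounded((uint32_t)deg[cur]);
        sent[2 * t + 1] = n_nodes + elab[pick];
        cur = nbr[pick];
        sent[2 * t + 2] = cur;
      }
      out[k++] = sent;
    }
  }
  return out;
}
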