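#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Degree-preserving double-edge-swap Markov chain on strongly connected
// digraphs.  Moves that would create a duplicate edge, a self-loop, or break
// strong connectivity are rejected; rejected attempts still advance the
// chain.  Edges are 0-based here; the R wrapper shifts indices.

namespace {

// xorshift32: small, fast, identical on every platform.
struct XorShift32 {
  uint32_t state;
  explicit XorShift32(uint32_t seed) : state(seed ? seed : 0x9e3779b9u) {}
  uint32_t next() {
    uint32_t x = state;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return state = x;
  }
  // unbiased draw in [0, m)
  uint32_t below(uint32_t m) {
    uint32_t lim = UINT32_MAX - (UINT32_MAX % m);
    uint32_t r;
    do { r = next(); } while (r >= lim);
    return r % m;
  }
};

struct Digraph {
  int n;
  std::vector<uint8_t> adj;             // n*n adjacency
  std::vector<std::vector<int>> out, in;
  bool has(int a, int b) const { return adj[(size_t)a * n + b] != 0; }
  void add(int a, int b) {
    adj[(size_t)a * n + b] = 1;
    out[a].push_back(b);
    in[b].push_back(a);
  }
  void drop(int a, int b) {
    adj[(size_t)a * n + b] = 0;
    auto rm = [](std::vector<int>& v, int x) {
      for (size_t i = 0; i < v.size(); ++i)
        if (v[i] == x) { v[i] = v.back(); v.pop_back(); return; }
    };
    rm(out[a], b);
    rm(in[b], a);
  }
};

// BFS over the given adjacency lists; true iff all n vertices reached from 0.
bool reaches_all(const std::vector<std::vector<int>>& nbr, int n,
                 std::vector<int>& queue, std::vector<uint8_t>& seen) {
  std::fill(seen.begin(), seen.end(), 0);
  queue.clear();
  queue.push_back(0);
  seen[0] = 1;
  int reached = 1;
  for (size_t head = 0; head < queue.size(); ++head) {
    int v = queue[head];
    for (int w : nbr[v]) {
      if (!seen[w]) {
        seen[w] = 1;
        ++reached;
        queue.push_back(w);
      }
    }
  }
  return reached == n;
}

bool strongly_connected(const Digraph& g, std::vector<int>& queue,
                        std::vector<uint8_t>& seen) {
  return reaches_all(g.out, g.n, queue, seen) &&
         reaches_all(g.in, g.n, queue, seen);
}

}  // namespace

// [[Rcpp::export]]
List swap_chain_cpp(int n, IntegerMatrix edges0, int n_swaps, int seed,
                    int snapshot_every) {
  int m = edges0.nrow();
  std::vector<std::pair<int, int>> edges(m);
  Digraph g;
  g.n = n;
  g.adj.assign((size_t)n * n, 0);
  g.out.assign(n, {});
  g.in.assign(n, {});
  for (int e = 0; e < m; ++e) {
    edges[e] = {edges0(e, 0), edges0(e, 1)};
    g.add(edges[e].first, edges[e].second);
  }
  std::vector<int> queue;
  queue.reserve(n);
  std::vector<uint8_t> seen(n);

  XorShift32 rng((uint32_t)seed * 2654435761u + 0x6d2b79f5u);
  List snapshots;
  int accepted = 0;

  auto snapshot = [&]() {
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
      out(e, 0) = edges[e].first;
      out(e, 1) = edges[e].second;
    }
    return out;
  };

  for (int step = 1; step <= n_swaps; ++step) {
    if (m >= 2) {
      int e1 = (int)rng.below((uint32_t)m);
      int e2 = (int)rng.below((uint32_t)m);
      if (e1 != e2) {
        int a = edges[e1].first, b = edges[e1].second;
        int c = edges[e2].first, d = edges[e2].second;
        if (a != c && b != d && a != d && c != b &&
            !g.has(a, d) && !g.has(c, b)) {
          g.drop(a, b);
          g.drop(c, d);
          g.add(a, d);
          g.add(c, b);
          if (strongly_connected(g, queue, seen)) {
            edges[e1] = {a, d};
            edges[e2] = {c, b};
            ++accepted;
          } else {
            g.drop(a, d);
            g.drop(c, b);
            g.add(a, b);
            g.add(c, d);
          }
        }
      }
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snapshots.push_back(snapshot());
    }
  }

  return List::create(_["edges"] = snapshot(),
                      _["accepted"] = accepted,
                      _["snapshots"] = snapshots);
}
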