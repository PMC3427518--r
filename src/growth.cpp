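#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// uniform integer in 0..n-1 using R's unbiased index sampler
static inline int unif_index(int n) {
  return (int) R_unif_index((double) n);
}

// Growth loop shared by the duplication-family models (DA, DAC, DACR, DACL).
// The inner loop is compiled because R-level adjacency bookkeeping dominates
// runtime for the thousands of simulations an ABC run needs.  All draws come
// from R's generator in a fixed order, so set.seed() reproduces runs and the
// degenerate mixtures (p exactly 0 or 1 skip the move-choice draw) replay
// the pure models' stream bit for bit.
//
// edge_move: 1 = uniform random node pairs (DACR), 2 = preferential from the
// new node (DACL); complementary: DAC-style one-of-pair survival.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_dup(int n_target, double delta, double alpha,
                           double p, double m, int edge_move,
                           bool complementary,
                           IntegerMatrix seed_edges, int seed_n) {
  std::vector< std::vector<int> > adj(n_target);
  std::vector<int> deg(n_target, 0);
  long total_deg = 0;

  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b); adj[b].push_back(a);
    deg[a]++; deg[b]++; total_deg += 2;
  };
  auto has_edge = [&](int a, int b) {
    int src = (deg[a] <= deg[b]) ? a : b;
    int tgt = (src == a) ? b : a;
    return std::find(adj[src].begin(), adj[src].end(), tgt) != adj[src].end();
  };
  auto remove_edge = [&](int a, int b) {
    adj[a].erase(std::find(adj[a].begin(), adj[a].end(), b));
    adj[b].erase(std::find(adj[b].begin(), adj[b].end(), a));
    deg[a]--; deg[b]--; total_deg -= 2;
  };

  for (int r = 0; r < seed_edges.nrow(); r++)
    add_edge(seed_edges(r, 0) - 1, seed_edges(r, 1) - 1);

  int n = seed_n;
  while (n < n_target) {
    bool dup;
    if (p >= 1.0) dup = true;
    else if (p <= 0.0) dup = false;
    else dup = unif_rand() < p;

    if (dup) {
      int u = unif_index(n);
      int v = n; n++;
      std::vector<int> nb = adj[u];        // snapshot: edits below are safe
      for (size_t i = 0; i < nb.size(); i++) {
        int k = nb[i];
        if (!complementary) {
          if (unif_rand() >= delta) add_edge(v, k);
        } else if (unif_rand() < delta) {
          if (unif_rand() < 0.5) {         // original loses, copy keeps
            remove_edge(u, k);
            add_edge(v, k);
          }                                // else copy loses: nothing
        } else {
          add_edge(v, k);
        }
      }
      if (unif_rand() < alpha) add_edge(u, v);
    } else {
      int v = n; n++;
      int k = (int) R::rpois(m);
      if (edge_move == 1) {
        // uniform pairs anywhere in the network; self-pairs and existing
        // edges are discarded without retry
        for (int j = 0; j < k; j++) {
          int x = unif_index(n);
          int y = unif_index(n);
          if (x != y && !has_edge(x, y)) add_edge(x, y);
        }
      } else {
        // preferential attachment from v; uniform fallback on an edgeless
        // graph; duplicate proposals discarded without retry
        if (k > n - 1) k = n - 1;
        for (int j = 0; j < k; j++) {
          int tgt;
          if (total_deg == 0) {
            tgt = unif_index(n - 1);
          } else {
            double r2 = unif_rand() * (double) total_deg;
            double acc = 0.0;
            tgt = n - 1;
            for (int i2 = 0; i2 < n; i2++) {
              acc += deg[i2];
              if (r2 < acc) { tgt = i2; break; }
            }
          }
          if (tgt != v && !has_edge(v, tgt)) add_edge(v, tgt);
        }
      }
    }
  }

  long n_edges = total_deg / 2;
  IntegerMatrix out(n_edges, 2);
  long row = 0;
  for (int i = 0; i < n_target; i++) {
    for (size_t j = 0; j < adj[i].size(); j++) {
      if (adj[i][j] > i) {
        out(row, 0) = i + 1;
        out(row, 1) = adj[i][j] + 1;
        row++;
      }
    }
  }
  return out;
}
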