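#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand), so a single set.seed()
// on the R side makes walks and training bitwise reproducible.

static inline bool has_edge(const std::vector<int>& sorted_nb, int x) {
  return std::binary_search(sorted_nb.begin(), sorted_nb.end(), x);
}

static inline int sample_discrete(const std::vector<double>& w, double total) {
  double r = unif_rand() * total, acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (r <= acc) return i;
  }
  return n - 1;
}

// Second-order biased random walks (return parameter p, in-out parameter q).
// From state (t -> v) the unnormalized weight of stepping to neighbor x of v
// is 1/p if x == t, 1 if x is adjacent to t, 1/q otherwise.
// adj: 0-based sorted adjacency lists; starts: 0-based start nodes.
// [[Rcpp::export]]
List rcpp_biased_walks(List adj, IntegerVector starts, int walk_length,
                       int walks_per_node, double p, double q) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }
  List out(starts.size() * walks_per_node);
  int k = 0;
  std::vector<double> w;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int si = 0; si < starts.size(); ++si) {
      int s = starts[si];
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      if (!nb[s].empty()) {
        int prev = s;
        int cur = nb[s][(int)(unif_rand() * nb[s].size()) % nb[s].size()];
        walk.push_back(cur);
        while ((int)walk.size() < walk_length) {
          const std::vector<int>& cand = nb[cur];
          if (cand.empty()) break;
          w.resize(cand.size());
          double total = 0.0;
          for (size_t j = 0; j < cand.size(); ++j) {
            int x = cand[j];
            double wt = (x == prev) ? 1.0 / p
                      : (has_edge(nb[prev], x) ? 1.0 : 1.0 / q);
            w[j] = wt;
            total += wt;
          }
          int nxt = cand[sample_discrete(w, total)];
          walk.push_back(nxt);
          prev = cur;
          cur = nxt;
        }
      }
      out[k++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

// One second-order transition distribution, for bias diagnostics/tests:
// probabilities over the neighbors of v given the walk came from t.
// [[Rcpp::export]]
NumericVector rcpp_transition_probs(List adj, int t, int v, double p, double q) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector x = adj[i];
    nb[i] = std::vector<int>(x.begin(), x.end());
  }
  const std::vector<int>& cand = nb[v];
  NumericVector out(cand.size());
  double total = 0.0;
  for (size_t j = 0; j < cand.size(); ++j) {
    int x = cand[j];
    double wt = (x == t) ? 1.0 / p : (has_edge(nb[t], x) ? 1.0 : 1.0 / q);
    out[j] = wt;
    total += wt;
  }
  for (R_xlen_t j = 0; j < out.size(); ++j) out[j] /= total;
  return out;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus (word2vec-style).
// walks: 0-based node index sequences; counts: per-node corpus frequencies
// (unigram table uses counts^0.75). Single-threaded, R-RNG-driven SGD with
// linearly decaying learning rate; returns the input (center) vectors.
// [[Rcpp::export]]
NumericMatrix rcpp_sgns(List walks, int n_nodes, NumericVector counts,
                        int dim, int window, int epochs, int negative,
                        double alpha) {
  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }
  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif_rand() - 0.5) / dim;

  std::vector<std::vector<int>> wk(walks.size());
  long long total_tokens = 0;
  for (int wi = 0; wi < walks.size(); ++wi) {
    IntegerVector w = walks[wi];
    wk[wi] = std::vector<int>(w.begin(), w.end());
    total_tokens += w.size();
  }
  total_tokens *= epochs;
  long long processed = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < wk.size(); ++wi) {
      const std::vector<int>& walk = wk[wi];
      int len = (int)walk.size();
      for (int ci = 0; ci < len; ++ci) {
        double lr = alpha * (1.0 - (double)processed / (total_tokens + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        int center = walk[ci];
        int b = (int)(unif_rand() * window);  // shrunk window, word2vec style
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int oi = ci + off;
          if (oi < 0 || oi >= len) continue;
          int context = walk[oi];
          double* __restrict__ v0 = &syn0[(size_t)center * dim];
          double* __restrict__ gr = grad.data();
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int tgt;
            double label;
            if (neg == 0) {
              tgt = context;
              label = 1.0;
            } else {
              double r = unif_rand() * tot;
              tgt = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (tgt >= n_nodes) tgt = n_nodes - 1;
              if (tgt == context) continue;
              label = 0.0;
            }
            double* __restrict__ v1 = &syn1[(size_t)tgt * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              gr[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += gr[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
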