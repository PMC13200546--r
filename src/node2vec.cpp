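#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Self-contained RNG (splitmix64 seeding + xorshift128+) so that walk
// generation and skip-gram training are bit-reproducible for a given seed,
// independently of R's RNG state and of each other.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline bool is_neighbor(const std::vector<int>& nbr,
                               const std::vector<int>& off, int u, int v) {
  // nbr slice for u is sorted; binary search for v
  int lo = off[u], hi = off[u + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (nbr[mid] == v) return true;
    if (nbr[mid] < v) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

// Biased second-order random walks. Adjacency in CSR form with sorted
// neighbor lists; `starts` are 0-based node indices (each repeated
// walks-per-node times by the caller). Transition probability from `cur`
// (having arrived from `prev`) to x is proportional to w(cur,x) * bias with
// bias = 1/p if x == prev, 1 if x ~ prev, 1/q otherwise. Walks stop early
// (padded with -1) only if a node has no neighbors.
// [[Rcpp::export]]
IntegerMatrix n2v_walks(IntegerVector offsets, IntegerVector nbrs,
                        NumericVector wts, IntegerVector starts,
                        int walk_length, double p, double q, double seed) {
  std::vector<int> off(offsets.begin(), offsets.end());
  std::vector<int> nbr(nbrs.begin(), nbrs.end());
  std::vector<double> wt(wts.begin(), wts.end());
  int n_walks = starts.size();
  IntegerMatrix walks(n_walks, walk_length);
  std::vector<double> prob;
  for (int wi = 0; wi < n_walks; ++wi) {
    // independent stream per walk: reproducible regardless of scheduling
    XRng rng(((uint64_t)seed << 20) ^ ((uint64_t)wi * 0x5DEECE66DULL + 11u));
    int cur = starts[wi];
    int prev = -1;
    walks(wi, 0) = cur;
    for (int step = 1; step < walk_length; ++step) {
      int beg = off[cur], end = off[cur + 1];
      int deg = end - beg;
      if (deg == 0) {
        for (int s = step; s < walk_length; ++s) walks(wi, s) = -1;
        break;
      }
      prob.resize(deg);
      double tot = 0.0;
      for (int t = 0; t < deg; ++t) {
        int x = nbr[beg + t];
        double bias;
        if (prev < 0) bias = 1.0;
        else if (x == prev) bias = 1.0 / p;
        else if (is_neighbor(nbr, off, prev, x)) bias = 1.0;
        else bias = 1.0 / q;
        tot += wt[beg + t] * bias;
        prob[t] = tot;
      }
      double u = rng.unif() * tot;
      int lo = 0, hi = deg - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (prob[mid] >= u) hi = mid; else lo = mid + 1;
      }
      prev = cur;
      cur = nbr[beg + lo];
      walks(wi, step) = cur;
    }
  }
  return walks;
}

// Skip-gram with negative sampling over node "sentences". Single-threaded,
// fixed iteration order, own RNG: bitwise deterministic for a given seed.
// Negative sampling uses the unigram distribution raised to 3/4. Returns the
// input (center) vectors, one row per node; nodes never seen in a walk keep
// their tiny random initialization and are zeroed by the R wrapper.
// [[Rcpp::export]]
NumericMatrix sgns_train(IntegerMatrix walks, int n_nodes, int dim,
                         int window, int negative, int epochs,
                         double alpha0, double seed) {
  int n_walks = walks.nrow(), wl = walks.ncol();
  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // noise distribution ~ freq^{0.75}, sampled by inverse CDF
  std::vector<double> cdf(n_nodes, 0.0);
  {
    std::vector<double> cnt(n_nodes, 0.0);
    for (int w = 0; w < n_walks; ++w)
      for (int t = 0; t < wl; ++t) {
        int v = walks(w, t);
        if (v >= 0) cnt[v] += 1.0;
      }
    double tot = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      tot += (cnt[v] > 0) ? std::pow(cnt[v], 0.75) : 0.0;
      cdf[v] = tot;
    }
    if (tot <= 0) tot = 1.0;
    for (int v = 0; v < n_nodes; ++v) cdf[v] /= tot;
  }
  auto sample_noise = [&](XRng& r) {
    double u = r.unif();
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] >= u) hi = mid; else lo = mid + 1;
    }
    return lo;
  };

  double total_steps = (double)epochs * n_walks * wl;
  double done = 0.0;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      for (int t = 0; t < wl; ++t) {
        done += 1.0;
        int center = walks(w, t);
        if (center < 0) continue;
        double alpha = alpha0 * (1.0 - done / (total_steps + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int b = rng.below(window);  // word2vec-style shrunk window
        for (int j = b - window; j <= window - b; ++j) {
          if (j == 0) continue;
          int tc = t + j;
          if (tc < 0 || tc >= wl) continue;
          int ctx = walks(w, tc);
          if (ctx < 0) continue;
          double* v_in = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              target = sample_noise(rng);
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
            double g;
            if (f > 6.0) g = (label - 1.0) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int d = 0; d < dim; ++d) grad[d] += g * v_out[d];
            for (int d = 0; d < dim; ++d) v_out[d] += g * v_in[d];
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
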