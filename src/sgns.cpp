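#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xorshift64* PRNG: deterministic, independent of R's RNG stream so the
// training loop is reproducible under a single seed.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a walk corpus.
// walks: integer matrix of 1-based node ids, 0 = padding.
// Returns the input-side embedding matrix (n_nodes x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train(IntegerMatrix walks, int n_nodes, int dim,
                         int window, int negatives, int epochs,
                         double alpha0, int seed) {
  const int n_walks = walks.nrow(), wl = walks.ncol();
  XorShift rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // unigram counts for the negative-sampling table (freq^0.75)
  std::vector<double> cnt(n_nodes, 0.0);
  long long n_tokens = 0;
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j) {
      int w = walks(i, j);
      if (w > 0) { cnt[w - 1] += 1.0; ++n_tokens; }
    }
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int v = 0; v < n_nodes; ++v) total += std::pow(cnt[v], 0.75);
    if (total <= 0) stop("empty walk corpus");
    double acc = std::pow(cnt[0], 0.75) / total;
    int v = 0;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > acc && v < n_nodes - 1) {
        ++v;
        acc += std::pow(cnt[v], 0.75) / total;
      }
    }
  }

  std::vector<float> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  std::vector<float> grad(dim);
  const double total_pairs = (double)epochs * n_tokens;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      for (int j = 0; j < wl; ++j) {
        int center = walks(i, j);
        if (center <= 0) continue;
        processed += 1.0;
        double alpha = alpha0 * (1.0 - processed / (total_pairs + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int b = rng.below(window);  // word2vec-style dynamic window
        for (int k = j - window + b; k <= j + window - b; ++k) {
          if (k < 0 || k >= wl || k == j) continue;
          int context = walks(i, k);
          if (context <= 0) continue;
          float *l1 = &syn0[(size_t)(center - 1) * dim];
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int d = 0; d <= negatives; ++d) {
            int target; double label;
            if (d == 0) { target = context - 1; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == context - 1) continue;
              label = 0.0;
            }
            float *l2 = &syn1[(size_t)target * dim];
            float f = 0.0f;
            for (int c = 0; c < dim; ++c) f += l1[c] * l2[c];
            float g = (float)((label - sigmoid(f)) * alpha);
            for (int c = 0; c < dim; ++c) grad[c] += g * l2[c];
            for (int c = 0; c < dim; ++c) l2[c] += g * l1[c];
          }
          for (int c = 0; c < dim; ++c) l1[c] += grad[c];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int c = 0; c < dim; ++c) out(v, c) = syn0[(size_t)v * dim + c];
  return out;
}
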