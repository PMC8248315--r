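#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and deterministic for a
// fixed seed. Follows the classic word2vec training scheme: dynamic window
// shrinking, unigram^0.75 negative-sampling distribution, linearly decaying
// learning rate, tabulated sigmoid. Hot loops use restrict-qualified float
// pointers and a manually unrolled dot product (strict FP ordering blocks
// auto-vectorization of reductions).

static inline uint64_t sm64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  Rng(uint64_t seed) {
    uint64_t x = seed;
    s0 = sm64(x); s1 = sm64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0; const uint64_t y = s1;
    s0 = y; x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline uint32_t bounded(uint32_t n) { return (uint32_t)(next() % n); }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

#define MAX_EXP 6.0
#define EXP_TABLE_SIZE 1000

// sentences: 0-based token ids; counts: token frequencies (for the negative
// sampling distribution). Returns the input-side vectors, one row per token.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List sentences, NumericVector counts, int dim,
                             int window, int epochs, int negative,
                             double alpha, double seed) {
  const int V = counts.size();
  Rng rng((uint64_t)(int64_t)seed * 0xA24BAED4963EE407ULL + 1442695040888963407ULL);

  // sigmoid lookup table
  std::vector<float> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[i] = (float)(e / (e + 1.0));
  }

  // cumulative unigram^0.75 table; negatives drawn by binary search
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int i = 0; i < V; ++i) { tot += std::pow(counts[i], 0.75); cum[i] = tot; }
  if (tot <= 0) stop("empty vocabulary");

  std::vector<float> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  // copy sentences out of R storage once; the per-token accessor on R
  // vectors is far too slow for the training loop
  long long train_words = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> sents(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    train_words += sv.size();
  }
  const long long total = train_words * (long long)epochs;
  long long processed = 0;
  const double start_alpha = alpha;
  double cur_alpha = alpha;

  std::vector<float> neu1e(dim);
  float *__restrict const s0p = syn0.data();
  float *__restrict const s1p = syn1.data();
  float *__restrict const ne = neu1e.data();

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int> &sent = sents[s];
      const int n = (int)sent.size();
      for (int pos = 0; pos < n; ++pos) {
        if (++processed % 10000 == 0) {
          cur_alpha = start_alpha * (1.0 - (double)processed / (total + 1));
          if (cur_alpha < start_alpha * 1e-4) cur_alpha = start_alpha * 1e-4;
          Rcpp::checkUserInterrupt();
        }
        const int word = sent[pos];
        const int b = (int)rng.bounded((uint32_t)window);
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          const int pos2 = pos - window + a;
          if (pos2 < 0 || pos2 >= n) continue;
          const int ctx = sent[pos2];
          float *__restrict v0 = s0p + (size_t)ctx * dim;
          for (int c = 0; c < dim; ++c) ne[c] = 0.0f;
          for (int d = 0; d <= negative; ++d) {
            int target, label;
            if (d == 0) { target = word; label = 1; }
            else {
              double r = rng.unif() * tot;
              int lo = 0, hi = V - 1;
              while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] < r) lo = mid + 1; else hi = mid;
              }
              target = lo; label = 0;
              if (target == word) continue;
            }
            float *__restrict v1 = s1p + (size_t)target * dim;
            float f0 = 0.0f, f1 = 0.0f, f2 = 0.0f, f3 = 0.0f;
            int c = 0;
            for (; c + 3 < dim; c += 4) {
              f0 += v0[c] * v1[c];
              f1 += v0[c + 1] * v1[c + 1];
              f2 += v0[c + 2] * v1[c + 2];
              f3 += v0[c + 3] * v1[c + 3];
            }
            for (; c < dim; ++c) f0 += v0[c] * v1[c];
            const float f = (f0 + f1) + (f2 + f3);
            float g;
            if (f > MAX_EXP) g = (float)((label - 1) * cur_alpha);
            else if (f < -MAX_EXP) g = (float)(label * cur_alpha);
            else {
              int ei = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              if (ei < 0) ei = 0;
              if (ei >= EXP_TABLE_SIZE) ei = EXP_TABLE_SIZE - 1;  // f == MAX_EXP edge
              g = (float)((label - expTable[ei]) * cur_alpha);
            }
            for (int c2 = 0; c2 < dim; ++c2) {
              ne[c2] += g * v1[c2];
              v1[c2] += g * v0[c2];
            }
          }
          for (int c2 = 0; c2 < dim; ++c2) v0[c2] += ne[c2];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int c = 0; c < dim; ++c)
      out(i, c) = syn0[(size_t)i * dim + c];
  return out;
}
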