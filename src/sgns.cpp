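#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, following the canonical word2vec
// reference implementation: dynamic window (uniform shrink), frequency
// subsampling, unigram^0.75 negative-sampling table, linear learning-rate
// decay, sigmoid lookup table. Single-threaded and driven by a private
// xorshift64* generator so a fixed seed gives bit-identical vectors.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t below(uint64_t n) { return next() % n; }
};

const int SIGMOID_TABLE_SIZE = 1000;
const double MAX_SIGMOID = 6.0;

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector counts, int dim,
                         int window, double subsample, int negative,
                         int epochs, double alpha0, double alpha_min,
                         int seed) {
  const int vocab = counts.size();
  if (vocab == 0) stop("empty vocabulary");
  double total_words = 0.0;
  for (int i = 0; i < vocab; ++i) total_words += counts[i];

  // sigmoid lookup
  std::vector<double> sigm(SIGMOID_TABLE_SIZE);
  for (int i = 0; i < SIGMOID_TABLE_SIZE; ++i) {
    double x = (i * 2.0 * MAX_SIGMOID) / SIGMOID_TABLE_SIZE - MAX_SIGMOID;
    sigm[i] = 1.0 / (1.0 + std::exp(-x));
  }
  auto sigmoid = [&](double x) -> double {
    if (x >= MAX_SIGMOID) return 1.0;
    if (x <= -MAX_SIGMOID) return 0.0;
    int i = (int)((x + MAX_SIGMOID) * SIGMOID_TABLE_SIZE / (2.0 * MAX_SIGMOID));
    if (i < 0) i = 0;
    if (i >= SIGMOID_TABLE_SIZE) i = SIGMOID_TABLE_SIZE - 1;
    return sigm[i];
  };

  // unigram^{0.75} negative-sampling table
  const int table_size = 1 << 20;
  std::vector<int> neg_table(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < vocab; ++i) z += std::pow((double)counts[i], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / z;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      neg_table[i] = w;
      if ((double)i / table_size > cum && w < vocab - 1) {
        ++w;
        cum += std::pow((double)counts[w], 0.75) / z;
      }
    }
  }

  // keep probability under frequency subsampling (word2vec formula)
  std::vector<double> keep(vocab, 1.0);
  if (subsample > 0) {
    for (int i = 0; i < vocab; ++i) {
      double f = counts[i] / total_words;
      double p = (std::sqrt(f / subsample) + 1.0) * (subsample / f);
      keep[i] = p < 1.0 ? p : 1.0;
    }
  }

  XorShift64 rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // init: input vectors uniform in [-0.5, 0.5]/dim, output vectors zero
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const int n_sent = sentences.size();
  // cache sentences as int vectors
  std::vector<std::vector<int>> sents(n_sent);
  double corpus_tokens = 0.0;
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    corpus_tokens += sv.size();
  }
  const double train_total = corpus_tokens * epochs + 1.0;

  std::vector<double> grad(dim);
  std::vector<int> kept;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sent = sents[s];
      kept.clear();
      for (size_t t = 0; t < sent.size(); ++t) {
        ++processed;
        int w = sent[t];
        if (keep[w] < 1.0 && rng.unif() > keep[w]) continue;
        kept.push_back(w);
      }
      double alpha = alpha0 * (1.0 - processed / train_total);
      if (alpha < alpha_min) alpha = alpha_min;
      const int n = (int)kept.size();
      for (int t = 0; t < n; ++t) {
        int center = kept[t];
        int b = (int)rng.below((uint64_t)window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int c = t + off;
          if (c < 0 || c >= n) continue;
          int context = kept[c];
          double* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              target = neg_table[rng.below((uint64_t)table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            double g = (label - sigmoid(dot)) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
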