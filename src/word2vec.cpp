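// Minimal deterministic word2vec (CBOW / skip-gram, negative sampling).
// Single-threaded on purpose: reproducibility under a fixed seed matters more
// here than raw speed, and walk corpora are small.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift64* — self-contained so results do not depend on R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint32_t bounded(uint32_t n) { return static_cast<uint32_t>(next() % n); }
};

const int SIGMOID_TABLE_SIZE = 1024;
const double MAX_SIGMOID = 6.0;

}  // namespace

// [[Rcpp::export(name = ".w2v_train_cpp")]]
NumericMatrix w2v_train_cpp(List sentences, int vocab_size, NumericVector counts,
                            int dim, int window, int epochs, double alpha,
                            int negative, bool cbow, int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // sigmoid lookup table, as in the reference implementations
  std::vector<double> sigmoid(SIGMOID_TABLE_SIZE);
  for (int i = 0; i < SIGMOID_TABLE_SIZE; ++i) {
    double x = (2.0 * MAX_SIGMOID * i) / SIGMOID_TABLE_SIZE - MAX_SIGMOID;
    sigmoid[i] = 1.0 / (1.0 + std::exp(-x));
  }
  auto sig = [&](double x) -> double {
    if (x >= MAX_SIGMOID) return 1.0;
    if (x <= -MAX_SIGMOID) return 0.0;
    int i = static_cast<int>((x + MAX_SIGMOID) * SIGMOID_TABLE_SIZE / (2.0 * MAX_SIGMOID));
    if (i < 0) i = 0;
    if (i >= SIGMOID_TABLE_SIZE) i = SIGMOID_TABLE_SIZE - 1;
    return sigmoid[i];
  };

  // negative-sampling table over counts^0.75
  const int TABLE = 1 << 17;
  std::vector<int> neg_table(TABLE);
  {
    double total = 0.0;
    for (int v = 0; v < vocab_size; ++v) total += std::pow(counts[v], 0.75);
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int i = 0; i < TABLE; ++i) {
      neg_table[i] = v;
      if ((i + 1.0) / TABLE > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (rng.unif() - 0.5) / dim;

  // pre-extract sentences as int vectors
  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (R_xlen_t i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    std::vector<int> v(s.begin(), s.end());
    total_words += static_cast<long long>(v.size());
    sents.push_back(std::move(v));
  }
  if (total_words == 0) stop("empty training corpus");

  const double alpha0 = alpha;
  const double min_alpha = alpha0 * 1e-4;
  long long trained = 0;
  const long long budget = total_words * static_cast<long long>(epochs);
  std::vector<double> neu1(dim), grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < sents.size(); ++si) {
      const std::vector<int>& sent = sents[si];
      const int n = static_cast<int>(sent.size());
      for (int pos = 0; pos < n; ++pos) {
        double lr = alpha0 * (1.0 - static_cast<double>(trained) / (budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++trained;
        const int w = sent[pos];
        const int b = static_cast<int>(rng.bounded(static_cast<uint32_t>(window)));
        const int lo = std::max(0, pos - (window - b));
        const int hi = std::min(n - 1, pos + (window - b));

        if (cbow) {
          int cn = 0;
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int j = lo; j <= hi; ++j) {
            if (j == pos) continue;
            const double* v0 = &syn0[static_cast<size_t>(sent[j]) * dim];
            for (int k = 0; k < dim; ++k) neu1[k] += v0[k];
            ++cn;
          }
          if (cn == 0) continue;
          for (int k = 0; k < dim; ++k) neu1[k] /= cn;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = w;
              label = 1.0;
            } else {
              target = neg_table[rng.bounded(TABLE)];
              if (target == w) continue;
              label = 0.0;
            }
            double* v1 = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += neu1[k] * v1[k];
            const double g = (label - sig(f)) * lr;
            for (int k = 0; k < dim; ++k) grad[k] += g * v1[k];
            for (int k = 0; k < dim; ++k) v1[k] += g * neu1[k];
          }
          for (int j = lo; j <= hi; ++j) {
            if (j == pos) continue;
            double* v0 = &syn0[static_cast<size_t>(sent[j]) * dim];
            for (int k = 0; k < dim; ++k) v0[k] += grad[k];
          }
        } else {  // skip-gram
          for (int j = lo; j <= hi; ++j) {
            if (j == pos) continue;
            double* v0 = &syn0[static_cast<size_t>(sent[j]) * dim];
            std::fill(grad.begin(), grad.end(), 0.0);
            for (int d = 0; d <= negative; ++d) {
              int target;
              double label;
              if (d == 0) {
                target = w;
                label = 1.0;
              } else {
                target = neg_table[rng.bounded(TABLE)];
                if (target == w) continue;
                label = 0.0;
              }
              double* v1 = &syn1[static_cast<size_t>(target) * dim];
              double f = 0.0;
              for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
              const double g = (label - sig(f)) * lr;
              for (int k = 0; k < dim; ++k) grad[k] += g * v1[k];
              for (int k = 0; k < dim; ++k) v1[k] += g * v0[k];
            }
            for (int k = 0; k < dim; ++k) v0[k] += grad[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
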