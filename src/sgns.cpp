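// Skip-gram with negative sampling over subword-composed input vectors.
// Input vectors are the mean of a word's character n-gram vectors (the
// whole-word key counts as one n-gram); the output (context) side indexes
// plain word vectors. Single-threaded with its own RNG so that a fixed seed
// reproduces the tables bit-for-bit.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sigmoidd(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List sgns_train_cpp(List sentences, List word_grams, int n_words, int n_grams,
                    NumericVector counts, int dim, int window, int negatives,
                    int epochs, double lr0, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> syn0(static_cast<size_t>(n_grams) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_words) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  // negative-sampling table: cumulative counts^0.75
  std::vector<double> cum(n_words);
  double tot = 0.0;
  for (int w = 0; w < n_words; ++w) {
    tot += std::pow(counts[w], 0.75);
    cum[w] = tot;
  }

  std::vector<std::vector<int> > grams(n_words);
  for (int w = 0; w < n_words; ++w) {
    IntegerVector g = word_grams[w];
    grams[w].reserve(g.size());
    for (int j = 0; j < g.size(); ++j) grams[w].push_back(g[j] - 1);
  }

  std::vector<std::vector<int> > sents(sentences.size());
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sv = sentences[s];
    sents[s].reserve(sv.size());
    for (int j = 0; j < sv.size(); ++j) sents[s].push_back(sv[j] - 1);
    total_tokens += sv.size();
  }

  NumericVector epoch_loss(epochs);
  std::vector<double> h(dim), neu1e(dim);
  long long processed = 0;
  const long long plan = total_tokens * static_cast<long long>(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long long n_pairs = 0;
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sent = sents[s];
      const int len = static_cast<int>(sent.size());
      for (int t = 0; t < len; ++t) {
        double lr = lr0 * (1.0 - static_cast<double>(processed) / (plan + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++processed;
        const int w = sent[t];
        const std::vector<int>& gw = grams[w];
        const double inv_g = 1.0 / gw.size();
        for (int d = 0; d < dim; ++d) h[d] = 0.0;
        for (size_t gi = 0; gi < gw.size(); ++gi) {
          const double* v = &syn0[static_cast<size_t>(gw[gi]) * dim];
          for (int d = 0; d < dim; ++d) h[d] += v[d];
        }
        for (int d = 0; d < dim; ++d) h[d] *= inv_g;

        const int win = 1 + static_cast<int>(rng() % window);
        for (int off = -win; off <= win; ++off) {
          if (off == 0) continue;
          const int j = t + off;
          if (j < 0 || j >= len) continue;
          const int ctx = sent[j];
          for (int d = 0; d < dim; ++d) neu1e[d] = 0.0;
          for (int k = 0; k <= negatives; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              const double r = unif(rng) * tot;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= n_words) target = n_words - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* vt = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += h[d] * vt[d];
            const double sg = sigmoidd(f);
            const double g = (label - sg) * lr;
            if (k == 0) {
              loss += -std::log(sg > 1e-10 ? sg : 1e-10);
              ++n_pairs;
            } else {
              loss += -std::log(1.0 - sg > 1e-10 ? 1.0 - sg : 1e-10);
            }
            for (int d = 0; d < dim; ++d) neu1e[d] += g * vt[d];
            for (int d = 0; d < dim; ++d) vt[d] += g * h[d];
          }
          const double scale = inv_g;
          for (size_t gi = 0; gi < gw.size(); ++gi) {
            double* v = &syn0[static_cast<size_t>(gw[gi]) * dim];
            for (int d = 0; d < dim; ++d) v[d] += neu1e[d] * scale;
          }
        }
      }
    }
    epoch_loss[ep] = n_pairs > 0 ? loss / n_pairs : NA_REAL;
  }

  NumericMatrix gm(n_grams, dim), cm(n_words, dim);
  for (int i = 0; i < n_grams; ++i)
    for (int d = 0; d < dim; ++d) gm(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  for (int i = 0; i < n_words; ++i)
    for (int d = 0; d < dim; ++d) cm(i, d) = syn1[static_cast<size_t>(i) * dim + d];
  return List::create(_["ngram_vec"] = gm, _["context_vec"] = cm,
                      _["epoch_loss"] = epoch_loss);
}
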