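// Skip-gram embedding with negative sampling (word2vec SGNS) over k-mer
// token streams. Deterministic for a fixed seed; single-threaded.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

// tokens: list of integer vectors of 0-based token ids (one per sequence)
// Returns V x dim matrix of input embeddings.
// [[Rcpp::export(name = ".cpp_sg_train")]]
arma::mat cpp_sg_train(List tokens, int vocab_size, int dim, int window,
                       int epochs, double lr0, int negative, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram counts -> negative-sampling table (counts^0.75)
  std::vector<double> counts(vocab_size, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < tokens.size(); ++s) {
    IntegerVector tv = tokens[s];
    for (int i = 0; i < tv.size(); ++i) {
      counts[tv[i]] += 1.0;
      ++total_tokens;
    }
  }
  std::vector<double> wts(vocab_size);
  for (int v = 0; v < vocab_size; ++v) wts[v] = std::pow(counts[v], 0.75);
  std::discrete_distribution<int> neg_dist(wts.begin(), wts.end());

  arma::mat W(vocab_size, dim), C(vocab_size, dim, arma::fill::zeros);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      W(v, d) = (unif(rng) - 0.5) / dim;

  const long long total_pairs_est =
      (long long)epochs * total_tokens * window;  // for lr decay
  long long processed = 0;

  // row-major copies so each embedding is contiguous for the scalar loops
  std::vector<double> Wr(vocab_size * dim), Cr(vocab_size * dim, 0.0);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d) Wr[(size_t)v * dim + d] = W(v, d);
  std::vector<double> grad_center(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < tokens.size(); ++s) {
      IntegerVector tv = tokens[s];
      int n = tv.size();
      for (int i = 0; i < n; ++i) {
        int b = 1 + (int)(unif(rng) * window);  // dynamic window
        if (b > window) b = window;
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          double lr = lr0 * std::max(1.0 - (double)processed / (total_pairs_est + 1), 1e-4);
          ++processed;
          int center = tv[i], ctx = tv[j];
          double* wc = &Wr[(size_t)center * dim];
          std::fill(grad_center.begin(), grad_center.end(), 0.0);
          // positive pair + `negative` sampled negatives
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = neg_dist(rng);
              if (target == ctx) continue;
              label = 0.0;
            }
            double* ct = &Cr[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += wc[d] * ct[d];
            double sig = 1.0 / (1.0 + std::exp(-f));
            double g = (label - sig) * lr;
            for (int d = 0; d < dim; ++d) {
              grad_center[d] += g * ct[d];
              ct[d] += g * wc[d];
            }
          }
          for (int d = 0; d < dim; ++d) wc[d] += grad_center[d];
        }
      }
    }
  }
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d) W(v, d) = Wr[(size_t)v * dim + d];
  return W;
}
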