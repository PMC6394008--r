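// Skip-gram with negative sampling (SGNS), single-threaded and fully
// deterministic given the seed: all sampling uses an internal xorshift64*
// stream, so identical corpus + seed always yields identical vectors.
// docs: list of 0-based integer vectors (tokens already restricted to the
// model vocabulary). unigram_table: 0-based word indices sampled for
// negatives (frequency^0.75 table built in R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline uint64_t xs64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s * 2685821657736338717ULL;
}

static inline double sigmoid1(double z) {
  if (z > 30) return 1.0;
  if (z < -30) return 0.0;
  return 1.0 / (1.0 + std::exp(-z));
}

// [[Rcpp::export]]
arma::mat sgns_train_cpp(const Rcpp::List &docs, int vocab_size, int dim,
                         int window, int negative, int epochs, double lr0,
                         const arma::ivec &unigram_table, int seed) {
  mat Win(dim, vocab_size), Wout(dim, vocab_size, fill::zeros);
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  for (uword j = 0; j < Win.n_elem; ++j) {
    Win[j] = (((xs64(rng) >> 11) * (1.0 / 9007199254740992.0)) - 0.5) / dim;
  }

  const int ndocs = docs.size();
  long long total_tokens = 0;
  std::vector<std::vector<int>> corpus(ndocs);
  for (int d = 0; d < ndocs; ++d) {
    corpus[d] = Rcpp::as<std::vector<int>>(docs[d]);
    total_tokens += corpus[d].size();
  }
  const long long train_total = std::max(1LL, total_tokens * epochs);
  const uword tbl = unigram_table.n_elem;

  vec err(dim);
  long long processed = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < ndocs; ++d) {
      const std::vector<int> &doc = corpus[d];
      const int L = doc.size();
      for (int i = 0; i < L; ++i) {
        double lr = lr0 * (1.0 - (double)processed / train_total);
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++processed;
        const int center = doc[i];
        for (int j = std::max(0, i - window);
             j <= std::min(L - 1, i + window); ++j) {
          if (j == i) continue;
          const int ctx = doc[j];
          err.zeros();
          // positive pair + `negative` sampled negatives
          for (int n = 0; n <= negative; ++n) {
            int target;
            double label;
            if (n == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = unigram_table[xs64(rng) % tbl];
              if (target == ctx) continue;
              label = 0.0;
            }
            double z = dot(Win.col(center), Wout.col(target));
            double g = (label - sigmoid1(z)) * lr;
            err += g * Wout.col(target);
            Wout.col(target) += g * Win.col(center);
          }
          Win.col(center) += err;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return Win.t();  // vocab_size x dim
}
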