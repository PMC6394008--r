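// Two-layer LSTM horizon classifier: forward pass, backpropagation through
// time, and Adam training loop. Parameter order in the weight list:
// W1 (4H x D), U1 (4H x H), b1 (4H x 1), W2 (4H x H), U2 (4H x H),
// b2 (4H x 1), V (K x H), c (K x 1). Gate row packing: input, forget,
// candidate, output. All randomness (init, shuffling) comes from R; this
// unit is purely deterministic arithmetic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

enum { iW1, iU1, ib1, iW2, iU2, ib2, iV, ic, NPAR };

static std::vector<mat> as_params(const Rcpp::List &w) {
  std::vector<mat> P(NPAR);
  for (int k = 0; k < NPAR; ++k) P[k] = Rcpp::as<mat>(w[k]);
  return P;
}

static Rcpp::List params_to_list(const std::vector<mat> &P) {
  Rcpp::List out(NPAR);
  out.names() = Rcpp::CharacterVector::create("W1", "U1", "b1", "W2", "U2",
                                              "b2", "V", "c");
  for (int k = 0; k < NPAR; ++k) out[k] = P[k];
  return out;
}

static inline mat sigmoid(const mat &z) { return 1.0 / (1.0 + exp(-z)); }

static void softmax_inplace(mat &z) {
  z.each_row() -= max(z, 0);
  z = exp(z);
  z.each_row() /= sum(z, 0);
}

struct Cache {
  std::vector<mat> x, i1, f1, g1, o1, c1, h1, i2, f2, g2, o2, c2, h2;
  explicit Cache(int T)
      : x(T), i1(T), f1(T), g1(T), o1(T), c1(T), h1(T), i2(T), f2(T), g2(T),
        o2(T), c2(T), h2(T) {}
};

// Forward through both layers for one batch; fills the cache.
static void forward(const cube &X, const uvec &idx,
                    const std::vector<mat> &P, Cache &cc) {
  const int T = X.n_cols;           // X: (D, T, N)
  const int D = X.n_rows;
  const int B = idx.n_elem;
  const int H = P[iU1].n_cols;
  mat h1p(H, B, fill::zeros), c1p(H, B, fill::zeros);
  mat h2p(H, B, fill::zeros), c2p(H, B, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat xt(D, B);
    for (int b = 0; b < B; ++b) xt.col(b) = X.slice(idx[b]).col(t);
    cc.x[t] = xt;

    mat a1 = P[iW1] * xt + P[iU1] * h1p;
    a1.each_col() += P[ib1].col(0);
    cc.i1[t] = sigmoid(a1.rows(0, H - 1));
    cc.f1[t] = sigmoid(a1.rows(H, 2 * H - 1));
    cc.g1[t] = tanh(a1.rows(2 * H, 3 * H - 1));
    cc.o1[t] = sigmoid(a1.rows(3 * H, 4 * H - 1));
    cc.c1[t] = cc.f1[t] % c1p + cc.i1[t] % cc.g1[t];
    cc.h1[t] = cc.o1[t] % tanh(cc.c1[t]);

    mat a2 = P[iW2] * cc.h1[t] + P[iU2] * h2p;
    a2.each_col() += P[ib2].col(0);
    cc.i2[t] = sigmoid(a2.rows(0, H - 1));
    cc.f2[t] = sigmoid(a2.rows(H, 2 * H - 1));
    cc.g2[t] = tanh(a2.rows(2 * H, 3 * H - 1));
    cc.o2[t] = sigmoid(a2.rows(3 * H, 4 * H - 1));
    cc.c2[t] = cc.f2[t] % c2p + cc.i2[t] % cc.g2[t];
    cc.h2[t] = cc.o2[t] % tanh(cc.c2[t]);

    h1p = cc.h1[t]; c1p = cc.c1[t];
    h2p = cc.h2[t]; c2p = cc.c2[t];
  }
}

// Cross-entropy loss and full gradients for one batch.
// y is 0-based class per batch element. all_steps averages the per-step
// losses instead of using the final step only.
static double backward(const cube &X, const uvec &idx, const ivec &y,
                       const std::vector<mat> &P, std::vector<mat> &G,
                       bool all_steps) {
  const int T = X.n_cols;
  const int B = idx.n_elem;
  const int H = P[iU1].n_cols;
  Cache cc(T);
  forward(X, idx, P, cc);

  for (int k = 0; k < NPAR; ++k) G[k] = zeros<mat>(size(P[k]));

  double loss = 0.0;
  const double stepw = all_steps ? 1.0 / T : 1.0;

  mat dh1(H, B, fill::zeros), dc1(H, B, fill::zeros);
  mat dh2(H, B, fill::zeros), dc2(H, B, fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    if (all_steps || t == T - 1) {
      mat logits = P[iV] * cc.h2[t];
      logits.each_col() += P[ic].col(0);
      softmax_inplace(logits);
      for (int b = 0; b < B; ++b) {
        const int yb = y[idx[b]];
        loss -= stepw * std::log(std::max(logits(yb, b), 1e-300)) / B;
        logits(yb, b) -= 1.0;
      }
      logits *= stepw / B;  // dlogits
      G[iV] += logits * cc.h2[t].t();
      G[ic].col(0) += sum(logits, 1);
      dh2 += P[iV].t() * logits;
    }

    // layer 2 cell backward
    mat tc2 = tanh(cc.c2[t]);
    mat dct = dh2 % cc.o2[t] % (1.0 - square(tc2)) + dc2;
    mat c2prev = (t > 0) ? cc.c2[t - 1] : zeros<mat>(H, B);
    mat dai = dct % cc.g2[t] % cc.i2[t] % (1.0 - cc.i2[t]);
    mat daf = dct % c2prev % cc.f2[t] % (1.0 - cc.f2[t]);
    mat dag = dct % cc.i2[t] % (1.0 - square(cc.g2[t]));
    mat dao = dh2 % tc2 % cc.o2[t] % (1.0 - cc.o2[t]);
    mat da2 = join_cols(join_cols(dai, daf), join_cols(dag, dao));
    mat h2prev = (t > 0) ? cc.h2[t - 1] : zeros<mat>(H, B);
    G[iW2] += da2 * cc.h1[t].t();
    G[iU2] += da2 * h2prev.t();
    G[ib2].col(0) += sum(da2, 1);
    dc2 = dct % cc.f2[t];
    dh2 = P[iU2].t() * da2;
    dh1 += P[iW2].t() * da2;  // gradient into layer-1 output at step t

    // layer 1 cell backward
    mat tc1 = tanh(cc.c1[t]);
    mat dct1 = dh1 % cc.o1[t] % (1.0 - square(tc1)) + dc1;
    mat c1prev = (t > 0) ? cc.c1[t - 1] : zeros<mat>(H, B);
    mat dai1 = dct1 % cc.g1[t] % cc.i1[t] % (1.0 - cc.i1[t]);
    mat daf1 = dct1 % c1prev % cc.f1[t] % (1.0 - cc.f1[t]);
    mat dag1 = dct1 % cc.i1[t] % (1.0 - square(cc.g1[t]));
    mat dao1 = dh1 % tc1 % cc.o1[t] % (1.0 - cc.o1[t]);
    mat da1 = join_cols(join_cols(dai1, daf1), join_cols(dag1, dao1));
    mat h1prev = (t > 0) ? cc.h1[t - 1] : zeros<mat>(H, B);
    G[iW1] += da1 * cc.x[t].t();
    G[iU1] += da1 * h1prev.t();
    G[ib1].col(0) += sum(da1, 1);
    dc1 = dct1 % cc.f1[t];
    dh1 = P[iU1].t() * da1;
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(const arma::cube &X, const arma::ivec &y,
                         const Rcpp::List &weights, bool all_steps) {
  std::vector<mat> P = as_params(weights), G(NPAR);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  double loss = backward(X, idx, y, P, G, all_steps);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(const arma::cube &X, const Rcpp::List &weights) {
  std::vector<mat> P = as_params(weights);
  const int N = X.n_slices;
  const int T = X.n_cols;
  const int K = P[iV].n_rows;
  mat probs(K, N);
  const int chunk = 256;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = regspace<uvec>(s, e - 1);
    Cache cc(T);
    forward(X, idx, P, cc);
    mat logits = P[iV] * cc.h2[T - 1];
    logits.each_col() += P[ic].col(0);
    softmax_inplace(logits);
    probs.cols(s, e - 1) = logits;
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube &X, const arma::ivec &y,
                          const Rcpp::List &weights,
                          const arma::umat &orders,  // N x epochs, 0-based
                          int batch_size, double lr, bool all_steps,
                          double beta1, double beta2, double eps) {
  std::vector<mat> P = as_params(weights), G(NPAR), M(NPAR), Vv(NPAR);
  for (int k = 0; k < NPAR; ++k) {
    M[k] = zeros<mat>(size(P[k]));
    Vv[k] = zeros<mat>(size(P[k]));
  }
  const int N = X.n_slices;
  const int epochs = orders.n_cols;
  vec epoch_loss(epochs, fill::zeros);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double tot = 0.0;
    int nb = 0;
    for (int s = 0; s < N; s += batch_size) {
      int e = std::min(N, s + batch_size);
      uvec idx = orders(span(s, e - 1), span(ep, ep));
      double l = backward(X, idx, y, P, G, all_steps);
      tot += l;
      ++nb;
      ++step;
      double corr = std::sqrt(1.0 - std::pow(beta2, (double)step)) /
                    (1.0 - std::pow(beta1, (double)step));
      for (int k = 0; k < NPAR; ++k) {
        M[k] = beta1 * M[k] + (1.0 - beta1) * G[k];
        Vv[k] = beta2 * Vv[k] + (1.0 - beta2) * square(G[k]);
        P[k] -= lr * corr * M[k] / (sqrt(Vv[k]) + eps);
      }
    }
    epoch_loss[ep] = tot / nb;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = params_to_list(P),
                            Rcpp::Named("epoch_loss") = epoch_loss);
}
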