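// Fully connected regression network: ReLU hidden layers, linear output,
// mean-squared-error loss, Adam updates on shuffled mini-batches. The
// trainer owns its RNG (same xoshiro generator as the transport kernel) so
// a given seed reproduces initial weights, batch order and hence the entire
// loss history.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_train_mlp(const arma::mat &X, const arma::mat &Y,
                   IntegerVector hidden, int epochs, int batch_size,
                   double learning_rate, double seed) {
  const arma::uword n = X.n_rows;
  std::vector<arma::uword> sizes;
  sizes.push_back(X.n_cols);
  for (int h : hidden) sizes.push_back(static_cast<arma::uword>(h));
  sizes.push_back(Y.n_cols);
  const size_t L = sizes.size() - 1;  // number of weight layers

  Rng rng(static_cast<uint64_t>(seed));

  // He-uniform initialisation, biases at zero
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    const double limit = std::sqrt(6.0 / static_cast<double>(sizes[l]));
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (arma::uword j = 0; j < W[l].n_cols; ++j)
      for (arma::uword i = 0; i < W[l].n_rows; ++i)
        W[l](i, j) = limit * (2.0 * rng.unif() - 1.0);
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    mW[l] = arma::mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    vW[l] = arma::mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    mb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    vb[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  NumericVector loss_history(epochs);
  std::vector<arma::mat> A(L + 1), Z(L);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the trainer's own stream
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = static_cast<arma::uword>(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    double ep_loss = 0.0;
    long n_batches = 0;
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      const arma::uword stop =
          std::min(n, start + static_cast<arma::uword>(batch_size));
      const arma::uword bs = stop - start;
      arma::uvec idx(bs);
      for (arma::uword i = 0; i < bs; ++i) idx[i] = order[start + i];

      A[0] = X.rows(idx);
      const arma::mat Yb = Y.rows(idx);

      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l + 1 < L) ? arma::clamp(Z[l], 0.0, arma::datum::inf)
                               : Z[l];
      }

      const arma::mat resid = A[L] - Yb;
      ep_loss += arma::accu(arma::square(resid)) /
                 static_cast<double>(resid.n_elem);
      ++n_batches;

      // backward pass (gradient of mean over batch elements)
      arma::mat delta =
          resid * (2.0 / static_cast<double>(resid.n_elem));
      ++step;
      const double corr1 = 1.0 - std::pow(beta1, step);
      const double corr2 = 1.0 - std::pow(beta2, step);
      for (size_t li = L; li-- > 0;) {
        const arma::mat gW = A[li].t() * delta;
        const arma::rowvec gb = arma::sum(delta, 0);
        if (li > 0) {
          delta = delta * W[li].t();
          delta %= arma::conv_to<arma::mat>::from(Z[li - 1] > 0.0);
        }
        mW[li] = beta1 * mW[li] + (1.0 - beta1) * gW;
        vW[li] = beta2 * vW[li] + (1.0 - beta2) * arma::square(gW);
        mb[li] = beta1 * mb[li] + (1.0 - beta1) * gb;
        vb[li] = beta2 * vb[li] + (1.0 - beta2) * arma::square(gb);
        W[li] -= learning_rate * (mW[li] / corr1) /
                 (arma::sqrt(vW[li] / corr2) + eps);
        b[li] -= learning_rate * (mb[li] / corr1) /
                 (arma::sqrt(vb[li] / corr2) + eps);
      }
    }
    loss_history[ep] = ep_loss / static_cast<double>(n_batches);
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = wrap(W[l]);
    bout[l] = wrap(arma::vec(b[l].t()));
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["loss_history"] = loss_history);
}

// Row-by-row forward pass (matrix-vector products throughout), so a batch
// prediction is element-wise identical to predicting each record alone.

// [[Rcpp::export]]
arma::mat cpp_mlp_forward(const arma::mat &X, List weights, List biases) {
  const size_t L = weights.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::vec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    b[l] = as<arma::vec>(biases[l]);
  }
  arma::mat out(X.n_rows, W[L - 1].n_cols);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::vec a = X.row(i).t();
    for (size_t l = 0; l < L; ++l) {
      a = W[l].t() * a + b[l];
      if (l + 1 < L) a = arma::clamp(a, 0.0, arma::datum::inf);
    }
    out.row(i) = a.t();
  }
  return out;
}
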