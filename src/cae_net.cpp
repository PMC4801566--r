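// Core training loops for continuous-autoencoder networks.
//
// A network is an ordered list of affine layers followed by the improved
// sigmoid f(a) = k * (1/(1 + exp(-c*a)) - 0.5).  During training a zero-mean
// Gaussian stochastic unit sigma*N(0,1) is added per unit to every
// pre-activation; the same draw is reused on the backward pass
// (reparameterisation-style: no gradient flows through sigma).
//
// All randomness (noise draws, per-epoch sample order, dropout masks) comes
// from R's RNG stream, so results are reproducible via set.seed() in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
  double k, c, sigma, lambda;
};

Net unpack(const List& Ws, const List& bs, double k, double c, double sigma,
           double lambda) {
  Net net;
  net.k = k; net.c = c; net.sigma = sigma; net.lambda = lambda;
  for (int l = 0; l < Ws.size(); ++l) {
    net.W.push_back(as<arma::mat>(Ws[l]));
    net.b.push_back(as<arma::vec>(bs[l]));
  }
  return net;
}

List pack(const Net& net) {
  List Ws(net.W.size()), bs(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    Ws[l] = net.W[l];
    bs[l] = net.b[l];
  }
  return List::create(_["W"] = Ws, _["b"] = bs);
}

// Forward pass for one sample.  h[0] is the input; h[l+1], s[l] are the
// activation and logistic factor of layer l.  s is kept because
// f'(a) = k*c*s*(1-s).  When dropout is active, mask[l] (values 0 or
// 1/(1-p)) multiplies the *output* of hidden layer l; the same factor is
// applied to f' on the way back.
double forward(const Net& net, const arma::vec& x, const arma::vec& y,
               bool noise, std::vector<arma::vec>& h,
               std::vector<arma::vec>& s,
               const std::vector<arma::vec>* mask = nullptr) {
  const size_t L = net.W.size();
  h.assign(L + 1, arma::vec());
  s.assign(L, arma::vec());
  h[0] = x;
  for (size_t l = 0; l < L; ++l) {
    arma::vec a = net.W[l] * h[l] + net.b[l];
    if (noise && net.sigma > 0.0) {
      for (arma::uword i = 0; i < a.n_elem; ++i)
        a[i] += net.sigma * norm_rand();
    }
    s[l] = 1.0 / (1.0 + arma::exp(-net.c * a));
    h[l + 1] = net.k * (s[l] - 0.5);
    if (mask != nullptr && l + 1 < L)
      h[l + 1] %= (*mask)[l];
  }
  arma::vec r = h[L] - y;
  return 0.5 * arma::dot(r, r);
}

// Backward pass for one sample; accumulates data-loss gradients into gW/gb
// (no weight-decay term -- callers add lambda*W themselves).
void backward(const Net& net, const arma::vec& y,
              const std::vector<arma::vec>& h,
              const std::vector<arma::vec>& s,
              std::vector<arma::mat>& gW, std::vector<arma::vec>& gb,
              const std::vector<arma::vec>* mask = nullptr) {
  const size_t L = net.W.size();
  arma::vec delta;
  for (size_t li = L; li-- > 0;) {
    arma::vec fp = net.k * net.c * (s[li] % (1.0 - s[li]));
    if (mask != nullptr && li + 1 < L)
      fp %= (*mask)[li];
    if (li == L - 1) {
      delta = (h[L] - y) % fp;
    } else {
      delta = (net.W[li + 1].t() * delta) % fp;
    }
    gW[li] += delta * h[li].t();
    gb[li] += delta;
  }
}

double decay_term(const Net& net) {
  double sq = 0.0;
  for (const arma::mat& W : net.W) sq += arma::accu(W % W);
  return 0.5 * net.lambda * sq;
}

// Deterministic (noise-off) mean data loss over rows of X.
double eval_loss(const Net& net, const arma::mat& X, const arma::mat& Y) {
  std::vector<arma::vec> h, s;
  double tot = 0.0;
  for (arma::uword i = 0; i < X.n_rows; ++i)
    tot += forward(net, X.row(i).t(), Y.row(i).t(), false, h, s);
  return tot / X.n_rows;
}

// Fisher-Yates permutation of 0..m-1 driven by R's RNG.
arma::uvec shuffled_indices(arma::uword m) {
  arma::uvec idx = arma::regspace<arma::uvec>(0, m - 1);
  for (arma::uword i = m - 1; i > 0; --i) {
    arma::uword j = static_cast<arma::uword>(unif_rand() * (i + 1));
    if (j > i) j = i;  // guard against unif_rand() == 1.0
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_net_gradients")]]
List cpp_net_gradients(List Ws, List bs, arma::mat X, arma::mat Y,
                       double k, double c, double sigma, double lambda,
                       bool train_mode) {
  Net net = unpack(Ws, bs, k, c, sigma, lambda);
  const size_t L = net.W.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  for (size_t l = 0; l < L; ++l) {
    gW[l].zeros(arma::size(net.W[l]));
    gb[l].zeros(arma::size(net.b[l]));
  }
  std::vector<arma::vec> h, s;
  double loss = 0.0;
  const arma::uword m = X.n_rows;
  for (arma::uword i = 0; i < m; ++i) {
    loss += forward(net, X.row(i).t(), Y.row(i).t(), train_mode, h, s);
    backward(net, Y.row(i).t(), h, s, gW, gb);
  }
  loss = loss / m + decay_term(net);
  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) {
    oW[l] = arma::mat(gW[l] / m + lambda * net.W[l]);
    ob[l] = arma::vec(gb[l] / m);
  }
  return List::create(_["W"] = oW, _["b"] = ob, _["loss"] = loss);
}

//' @noRd
// [[Rcpp::export(name = "cpp_forward")]]
arma::mat cpp_forward(List Ws, List bs, arma::mat X, double k, double c,
                      double sigma, bool train_mode) {
  Net net = unpack(Ws, bs, k, c, sigma, 0.0);
  std::vector<arma::vec> h, s;
  arma::mat out(X.n_rows, net.b.back().n_elem);
  arma::vec dummy = arma::zeros<arma::vec>(net.b.back().n_elem);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    forward(net, X.row(i).t(), dummy, train_mode, h, s);
    out.row(i) = h.back().t();
  }
  return out;
}

// Per-sample SGD with optional early break (FSGD).  Visits the samples in a
// fresh seeded random order each epoch and performs one update per sample.
// The monitored loss is the epoch mean of the per-sample data losses seen
// during the pass (plus the weight-decay term at end of epoch), or the
// deterministic loss on a held-out monitor set when Xmon is non-empty.
//
//' @noRd
// [[Rcpp::export(name = "cpp_sgd_train")]]
List cpp_sgd_train(List Ws, List bs, arma::mat X, arma::mat Y,
                   double k, double c, double sigma, double lambda,
                   int n_epochs, double alpha, double epsilon, int Kwin,
                   bool use_break, bool reset_counter,
                   arma::mat Xmon, arma::mat Ymon) {
  Net net = unpack(Ws, bs, k, c, sigma, lambda);
  const size_t L = net.W.size();
  const arma::uword m = X.n_rows;
  const bool holdout = Xmon.n_rows > 0;
  std::vector<arma::vec> h, s;
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  arma::vec losses(n_epochs);
  int counter = 0, break_epoch = n_epochs;
  bool broke = false;

  for (int ep = 0; ep < n_epochs; ++ep) {
    arma::uvec order = shuffled_indices(m);
    double ep_loss = 0.0;
    for (arma::uword t = 0; t < m; ++t) {
      const arma::uword i = order[t];
      ep_loss += forward(net, X.row(i).t(), Y.row(i).t(), true, h, s);
      for (size_t l = 0; l < L; ++l) {
        gW[l].zeros(arma::size(net.W[l]));
        gb[l].zeros(arma::size(net.b[l]));
      }
      backward(net, Y.row(i).t(), h, s, gW, gb);
      for (size_t l = 0; l < L; ++l) {
        net.W[l] -= alpha * (gW[l] + lambda * net.W[l]);
        net.b[l] -= alpha * gb[l];
      }
    }
    double monitored = holdout ? eval_loss(net, Xmon, Ymon) + decay_term(net)
                               : ep_loss / m + decay_term(net);
    losses[ep] = monitored;
    if (use_break) {
      if (monitored <= epsilon) {
        ++counter;
      } else if (reset_counter) {
        counter = 0;
      }
      if (counter >= Kwin) {
        break_epoch = ep + 1;
        broke = true;
        break;
      }
    }
  }
  List out = pack(net);
  out["losses"] = arma::vec(losses.head(break_epoch));
  out["break_epoch"] = break_epoch;
  out["broke_early"] = broke;
  return out;
}

// Batched backprop fine-tuning with momentum and inverted dropout on the
// hidden layers, sharing the FSGD break rule.  Velocity update:
// v <- momentum*v - alpha*grad; theta <- theta + v.
//
//' @noRd
// [[Rcpp::export(name = "cpp_batch_train")]]
List cpp_batch_train(List Ws, List bs, arma::mat X, arma::mat Y,
                     double k, double c, double sigma, double lambda,
                     int n_epochs, double alpha, double momentum,
                     double dropout, int batch_size, double epsilon,
                     int Kwin, bool use_break, bool reset_counter) {
  Net net = unpack(Ws, bs, k, c, sigma, lambda);
  const size_t L = net.W.size();
  const arma::uword m = X.n_rows;
  std::vector<arma::vec> h, s;
  std::vector<arma::mat> gW(L), vW(L);
  std::vector<arma::vec> gb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    vW[l].zeros(arma::size(net.W[l]));
    vb[l].zeros(arma::size(net.b[l]));
  }
  const bool use_mask = dropout > 0.0;
  const double keep = 1.0 - dropout;
  std::vector<arma::vec> mask(L >= 1 ? L - 1 : 0);
  arma::vec losses(n_epochs);
  int counter = 0, break_epoch = n_epochs;
  bool broke = false;

  for (int ep = 0; ep < n_epochs; ++ep) {
    arma::uvec order = shuffled_indices(m);
    double ep_loss = 0.0;
    for (arma::uword start = 0; start < m;
         start += static_cast<arma::uword>(batch_size)) {
      const arma::uword stop = std::min(
          m, start + static_cast<arma::uword>(batch_size));
      const arma::uword nb = stop - start;
      for (size_t l = 0; l < L; ++l) {
        gW[l].zeros(arma::size(net.W[l]));
        gb[l].zeros(arma::size(net.b[l]));
      }
      for (arma::uword t = start; t < stop; ++t) {
        const arma::uword i = order[t];
        const std::vector<arma::vec>* mp = nullptr;
        if (use_mask) {
          for (size_t l = 0; l + 1 < L; ++l) {
            mask[l].set_size(net.b[l].n_elem);
            for (arma::uword u = 0; u < mask[l].n_elem; ++u)
              mask[l][u] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          }
          mp = &mask;
        }
        ep_loss += forward(net, X.row(i).t(), Y.row(i).t(), true, h, s, mp);
        backward(net, Y.row(i).t(), h, s, gW, gb, mp);
      }
      for (size_t l = 0; l < L; ++l) {
        vW[l] = momentum * vW[l] - alpha * (gW[l] / nb + lambda * net.W[l]);
        vb[l] = momentum * vb[l] - alpha * (gb[l] / nb);
        net.W[l] += vW[l];
        net.b[l] += vb[l];
      }
    }
    double monitored = ep_loss / m + decay_term(net);
    losses[ep] = monitored;
    if (use_break) {
      if (monitored <= epsilon) {
        ++counter;
      } else if (reset_counter) {
        counter = 0;
      }
      if (counter >= Kwin) {
        break_epoch = ep + 1;
        broke = true;
        break;
      }
    }
  }
  List out = pack(net);
  out["losses"] = arma::vec(losses.head(break_epoch));
  out["break_epoch"] = break_epoch;
  out["broke_early"] = broke;
  return out;
}
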