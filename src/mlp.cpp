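// Feed-forward regression network: dense ReLU hidden layers, linear output,
// mean-squared-error loss, RMSprop optimizer, mini-batch training with
// per-epoch shuffling, optional validation split with early stopping and
// best-weight restoration.  All randomness comes from R's RNG so results
// are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Glorot-uniform initial weights drawn from R's RNG
arma::mat glorot(int n_in, int n_out) {
  double lim = std::sqrt(6.0 / (n_in + n_out));
  arma::mat w(n_in, n_out);
  for (arma::uword j = 0; j < w.n_cols; ++j)
    for (arma::uword i = 0; i < w.n_rows; ++i)
      w(i, j) = R::runif(-lim, lim);
  return w;
}

arma::uvec r_permutation(int n) {
  // Fisher-Yates with R uniforms
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
};

arma::vec forward(const Net& net, const arma::mat& X) {
  arma::mat a = X;
  int L = net.W.size();
  for (int l = 0; l < L - 1; ++l) {
    a = a * net.W[l];
    a.each_row() += net.b[l];
    a.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  a = a * net.W[L - 1];
  a.each_row() += net.b[L - 1];
  return a.col(0);
}

}  // namespace

// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat& X, const arma::vec& y,
                   IntegerVector hidden, int epochs, int batch_size,
                   double learning_rate, double rho, double epsilon,
                   double decay, double validation_split, int patience) {
  RNGScope scope;
  int n = X.n_rows, p = X.n_cols;

  std::vector<int> widths;
  widths.push_back(p);
  for (int h : hidden) widths.push_back(h);
  widths.push_back(1);
  int L = (int)widths.size() - 1;

  Net net;
  std::vector<arma::mat> cW(L);
  std::vector<arma::rowvec> cb(L);
  for (int l = 0; l < L; ++l) {
    net.W.push_back(glorot(widths[l], widths[l + 1]));
    net.b.push_back(arma::rowvec(widths[l + 1], arma::fill::zeros));
    cW[l] = arma::mat(widths[l], widths[l + 1], arma::fill::zeros);
    cb[l] = arma::rowvec(widths[l + 1], arma::fill::zeros);
  }

  // one initial shuffle, then the trailing fraction is held out
  arma::uvec perm = r_permutation(n);
  int n_val = (int)std::round(validation_split * n);
  int n_tr = n - n_val;
  arma::mat Xtr = X.rows(perm.head(n_tr));
  arma::vec ytr = y.elem(perm.head(n_tr));
  arma::mat Xval, yval_m;
  arma::vec yval;
  if (n_val > 0) {
    Xval = X.rows(perm.tail(n_val));
    yval = y.elem(perm.tail(n_val));
  }

  std::vector<double> hist_tr, hist_val;
  double best_val = R_PosInf;
  int best_epoch = -1, wait = 0;
  Net best = net;

  std::vector<arma::mat> act(L + 1), delta(L);

  for (int ep = 0; ep < epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    double lr = learning_rate / (1.0 + decay * ep);
    arma::uvec order = r_permutation(n_tr);
    double loss_sum = 0.0;
    for (int start = 0; start < n_tr; start += batch_size) {
      int stop = std::min(start + batch_size, n_tr) - 1;
      arma::uvec idx = order.subvec(start, stop);
      int m = (int)idx.n_elem;
      act[0] = Xtr.rows(idx);
      for (int l = 0; l < L; ++l) {
        act[l + 1] = act[l] * net.W[l];
        act[l + 1].each_row() += net.b[l];
        if (l < L - 1)
          act[l + 1].transform([](double v) { return v > 0.0 ? v : 0.0; });
      }
      arma::vec err = act[L].col(0) - ytr.elem(idx);
      loss_sum += arma::dot(err, err);
      // backprop, dL/dyhat = 2 err / m
      delta[L - 1] = arma::mat(err * (2.0 / m));
      for (int l = L - 2; l >= 0; --l) {
        delta[l] = delta[l + 1] * net.W[l + 1].t();
        delta[l] %= arma::conv_to<arma::mat>::from(act[l + 1] > 0.0);
      }
      for (int l = 0; l < L; ++l) {
        arma::mat gW = act[l].t() * delta[l];
        arma::rowvec gb = arma::sum(delta[l], 0);
        cW[l] = rho * cW[l] + (1.0 - rho) * arma::square(gW);
        cb[l] = rho * cb[l] + (1.0 - rho) * arma::square(gb);
        net.W[l] -= lr * gW / (arma::sqrt(cW[l]) + epsilon);
        net.b[l] -= lr * gb / (arma::sqrt(cb[l]) + epsilon);
      }
    }
    double tr_loss = loss_sum / n_tr;
    hist_tr.push_back(tr_loss);
    if (n_val > 0) {
      arma::vec pv = forward(net, Xval);
      double vl = arma::mean(arma::square(pv - yval));
      hist_val.push_back(vl);
      if (vl < best_val - 1e-12) {
        best_val = vl;
        best_epoch = ep;
        best = net;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
  }
  if (n_val > 0 && best_epoch >= 0) net = best;

  List Ws(L), bs(L);
  for (int l = 0; l < L; ++l) {
    Ws[l] = net.W[l];
    bs[l] = arma::rowvec(net.b[l]);
  }
  return List::create(
      _["weights"] = Ws, _["biases"] = bs,
      _["loss"] = hist_tr, _["val_loss"] = hist_val,
      _["best_epoch"] = best_epoch + 1, _["n_train"] = n_tr,
      _["n_val"] = n_val);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(List weights, List biases, const arma::mat& X) {
  Net net;
  int L = weights.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    net.b.push_back(as<arma::rowvec>(biases[l]));
  }
  return forward(net, X);
}
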