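// Training loop for the feedforward softmax classifier.
// Architecture: [linear -> (batchnorm) -> ReLU -> (dropout)]* -> linear -> softmax,
// minimizing class-weighted categorical cross-entropy by plain minibatch SGD
// with a step learning-rate schedule. All randomness (init, shuffling,
// dropout) comes from R's RNG so fits are bit-reproducible given a seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;

static void relu_inplace(mat& Z) {
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// Fisher-Yates shuffle driven by R's RNG (matches determinism contract)
static uvec r_permutation(int n) {
  uvec p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// [[Rcpp::export]]
List mlp_train(const arma::mat& X, const arma::mat& Y,
               const arma::vec& wi, IntegerVector hidden,
               bool batchnorm, double dropout,
               double lr0, double lr_factor, double lr_step,
               int epochs, int batch_size) {
  const int n = X.n_rows, d = X.n_cols, K = Y.n_cols;
  const int L = hidden.size() + 1;  // weight layers
  const double eps = 1e-5, mom = 0.1;

  std::vector<int> dims(L + 1);
  dims[0] = d;
  for (int l = 0; l < hidden.size(); ++l) dims[l + 1] = hidden[l];
  dims[L] = K;

  std::vector<mat> W(L);
  std::vector<rowvec> b(L), gam(L), bet(L), rmean(L), rvar(L);
  for (int l = 0; l < L; ++l) {
    double lim = std::sqrt(6.0 / dims[l]);
    W[l].set_size(dims[l], dims[l + 1]);
    // column-major fill matches R's matrix(runif(...)) layout
    for (arma::uword i = 0; i < W[l].n_elem; ++i)
      W[l](i) = (2.0 * unif_rand() - 1.0) * lim;
    b[l] = rowvec(dims[l + 1], arma::fill::zeros);
    if (batchnorm && l < L - 1) {
      gam[l] = rowvec(dims[l + 1], arma::fill::ones);
      bet[l] = rowvec(dims[l + 1], arma::fill::zeros);
      rmean[l] = rowvec(dims[l + 1], arma::fill::zeros);
      rvar[l] = rowvec(dims[l + 1], arma::fill::ones);
    }
  }

  NumericVector loss_hist(epochs);
  std::vector<mat> A(L), Zhat(L), Zt(L), mask(L);
  std::vector<rowvec> bstd(L);

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(lr_factor, std::floor(ep / lr_step));
    uvec ord = r_permutation(n);
    double tot_loss = 0.0; long tot_n = 0;
    for (int lo = 0; lo < n; lo += batch_size) {
      int hi = std::min(lo + batch_size, n) - 1;
      uvec idx = ord.subvec(lo, hi);
      int m = idx.n_elem;
      mat Acur = X.rows(idx);
      // ---- forward ----
      for (int l = 0; l < L - 1; ++l) {
        A[l] = Acur;
        mat Z = Acur * W[l];
        Z.each_row() += b[l];
        if (batchnorm) {
          rowvec mu = arma::mean(Z, 0);
          rowvec v = arma::mean(arma::square(Z), 0) - arma::square(mu);
          bstd[l] = arma::sqrt(v + eps);
          Z.each_row() -= mu;
          Z.each_row() /= bstd[l];
          Zhat[l] = Z;
          Z.each_row() %= gam[l];
          Z.each_row() += bet[l];
          rmean[l] = (1.0 - mom) * rmean[l] + mom * mu;
          rvar[l] = (1.0 - mom) * rvar[l] + mom * v;
        }
        Zt[l] = Z;
        relu_inplace(Z);
        if (dropout > 0.0) {
          mat mk(m, Z.n_cols);
          const double keep = 1.0 - dropout;
          for (arma::uword i = 0; i < mk.n_elem; ++i)
            mk(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          Z %= mk;
          mask[l] = mk;
        }
        Acur = Z;
      }
      mat Zout = Acur * W[L - 1];
      Zout.each_row() += b[L - 1];
      arma::vec zmax = arma::max(Zout, 1);
      Zout.each_col() -= zmax;
      mat P = arma::exp(Zout);
      P.each_col() /= arma::sum(P, 1);
      arma::vec wb = wi.elem(idx);
      // weighted cross-entropy on the true-class probabilities
      double batch_loss = 0.0;
      for (int i = 0; i < m; ++i) {
        arma::uword yi = arma::index_max(Y.row(idx[i]));
        double p = std::max(P(i, yi), 1e-12);
        batch_loss -= wb[i] * std::log(p);
      }
      if (!std::isfinite(batch_loss))
        stop("non-finite training loss at epoch %d (lr = %g)", ep + 1, lr);
      tot_loss += batch_loss; tot_n += m;
      // ---- backward ----
      mat dZ = (P - Y.rows(idx));
      dZ.each_col() %= wb / m;
      // Acur still holds the last hidden activation (input to output layer)
      mat gWL = Acur.t() * dZ;
      rowvec gbL = arma::sum(dZ, 0);
      mat dA = dZ * W[L - 1].t();
      W[L - 1] -= lr * gWL;
      b[L - 1] -= lr * gbL;
      for (int l = L - 2; l >= 0; --l) {
        mat dH = dA;
        if (dropout > 0.0) dH %= mask[l];
        // ReLU gate on the pre-activation
        dH %= arma::conv_to<mat>::from(Zt[l] > 0.0);
        if (batchnorm) {
          rowvec dgamma = arma::sum(dH % Zhat[l], 0);
          rowvec dbeta = arma::sum(dH, 0);
          dH.each_row() %= gam[l];           // now dZhat
          rowvec mh = arma::mean(dH, 0);
          rowvec mhz = arma::mean(dH % Zhat[l], 0);
          dH.each_row() -= mh;
          dH -= Zhat[l].each_row() % mhz;
          dH.each_row() /= bstd[l];
          gam[l] -= lr * dgamma;
          bet[l] -= lr * dbeta;
        }
        mat gWl = A[l].t() * dH;
        rowvec gbl = arma::sum(dH, 0);
        if (l > 0) dA = dH * W[l].t();
        W[l] -= lr * gWl;
        b[l] -= lr * gbl;
      }
    }
    loss_hist[ep] = tot_loss / tot_n;
  }

  List params(L);
  for (int l = 0; l < L; ++l) {
    List layer = List::create(Named("W") = wrap(W[l]),
                              Named("b") = NumericVector(b[l].begin(), b[l].end()));
    if (batchnorm && l < L - 1) {
      layer["bn"] = List::create(
        Named("gamma") = NumericVector(gam[l].begin(), gam[l].end()),
        Named("beta") = NumericVector(bet[l].begin(), bet[l].end()),
        Named("mean") = NumericVector(rmean[l].begin(), rmean[l].end()),
        Named("var") = NumericVector(rvar[l].begin(), rvar[l].end()));
    }
    params[l] = layer;
  }
  return List::create(Named("params") = params, Named("loss") = loss_hist);
}
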