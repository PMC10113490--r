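// Mini-batch Adam training loop for the fully connected ReLU network.
// Mirrors the R reference implementation (mlp_forward_cached /
// mlp_backward / adam_step) exactly; the R functions remain the
// documented reference and serve as the cross-check in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat& Xtr, const arma::mat& Ytr,
                   const arma::mat& Xva, const arma::mat& Yva,
                   List W0, List b0,
                   const arma::vec& lrs, int batch_size,
                   const LogicalVector& trainable,
                   double beta1, double beta2, double eps) {
  const int L = W0.size();
  const int m = Xtr.n_rows;
  const int n_epochs = lrs.n_elem;
  const int bs = std::min(batch_size, m);
  const int n_batch = (m + bs - 1) / bs;

  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = as<arma::rowvec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(1, b[l].n_elem);
    vb[l].zeros(1, b[l].n_elem);
  }

  arma::vec hist_train(n_epochs), hist_val(n_epochs);
  std::vector<arma::mat> A(L + 1), dWg(L);
  std::vector<arma::rowvec> dbg(L);
  long t_adam = 0;
  const double ycols = Ytr.n_cols;
  Function sample_int("sample.int");

  for (int epoch = 0; epoch < n_epochs; ++epoch) {
    // permutation from R's RNG so runs are seed-reproducible from R
    arma::uvec perm;
    if (n_batch > 1) {
      IntegerVector p = sample_int(m);
      perm.set_size(m);
      for (int i = 0; i < m; ++i) perm[i] = p[i] - 1;
    }
    const double lr = lrs[epoch];
    double loss_acc = 0.0;

    for (int bidx = 0; bidx < n_batch; ++bidx) {
      const int lo = bidx * bs;
      const int hi = std::min((bidx + 1) * bs, m) - 1;
      arma::mat Xb, Yb;
      if (n_batch > 1) {
        arma::uvec rows = perm.subvec(lo, hi);
        Xb = Xtr.rows(rows);
        Yb = Ytr.rows(rows);
      } else {
        Xb = Xtr;
        Yb = Ytr;
      }

      // forward with cached activations
      A[0] = Xb;
      for (int l = 0; l < L; ++l) {
        A[l + 1] = A[l] * W[l];
        A[l + 1].each_row() += b[l];
        if (l < L - 1) A[l + 1].transform([](double z) { return z > 0 ? z : 0.0; });
      }
      arma::mat diff = A[L] - Yb;
      loss_acc += arma::accu(arma::square(diff));

      // backward
      arma::mat dZ = (2.0 / (Xb.n_rows * ycols)) * diff;
      for (int l = L - 1; l >= 0; --l) {
        if (trainable[l]) {
          dWg[l] = A[l].t() * dZ;
          dbg[l] = arma::sum(dZ, 0);
        }
        if (l > 0) {
          dZ = dZ * W[l].t();
          dZ %= arma::conv_to<arma::mat>::from(A[l] > 0);
        }
      }

      // Adam
      ++t_adam;
      const double bc1 = 1.0 - std::pow(beta1, (double)t_adam);
      const double bc2 = 1.0 - std::pow(beta2, (double)t_adam);
      for (int l = 0; l < L; ++l) {
        if (!trainable[l]) continue;
        mW[l] = beta1 * mW[l] + (1 - beta1) * dWg[l];
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(dWg[l]);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * dbg[l];
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(dbg[l]);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
    hist_train[epoch] = loss_acc / (m * ycols);

    if (Xva.n_rows > 0) {
      arma::mat Av = Xva;
      for (int l = 0; l < L; ++l) {
        Av = Av * W[l];
        Av.each_row() += b[l];
        if (l < L - 1) Av.transform([](double z) { return z > 0 ? z : 0.0; });
      }
      hist_val[epoch] = arma::accu(arma::square(Av - Yva)) / (Yva.n_rows * ycols);
    } else {
      hist_val[epoch] = NA_REAL;
    }
    if (!std::isfinite(hist_train[epoch])) {
      stop("training diverged (loss not finite) at epoch %d", epoch + 1);
    }
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = wrap(W[l]);
    bout[l] = wrap(b[l]);
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_mse"] = hist_train, _["val_mse"] = hist_val);
}
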