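// Dense numeric kernels for the relation network.
//
// Layout convention: a batch of nwin windows of temporal length L with c
// channels is a (c x L*nwin) matrix, windows concatenated column-wise.
// Temporal convolution (stride 1, same padding, odd kernel k) is computed
// as one nearly-full-width GEMM per kernel tap followed by small
// corrections at the nwin-1 interior window boundaries, so no shifted
// copy of the input is ever materialised. Backward passes recompute
// cheap intermediates from the cached layer inputs instead of storing
// activation-sized caches.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---- temporal convolution ----

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& X, const int L, const arma::mat& W,
                       const arma::vec& b, const int k) {
  const int nc = X.n_cols, cin = X.n_rows, cout = W.n_rows;
  const int half = (k - 1) / 2, nwin = nc / L;
  arma::mat Y(cout, nc);
  Y.each_col() = b;
  for (int j = 0; j < k; ++j) {
    const int off = j - half;
    const arma::mat Wj = W.cols(j * cin, (j + 1) * cin - 1);
    if (off == 0) {
      Y += Wj * X;
    } else if (off > 0) {
      Y.cols(0, nc - 1 - off) += Wj * X.cols(off, nc - 1);
      for (int w = 1; w < nwin; ++w)               // undo cross-window taps
        for (int d = 1; d <= off; ++d)
          Y.col(w * L - d) -= Wj * X.col(w * L - d + off);
    } else {
      const int a = -off;
      Y.cols(a, nc - 1) += Wj * X.cols(0, nc - 1 - a);
      for (int w = 1; w < nwin; ++w)
        for (int d = 0; d < a; ++d)
          Y.col(w * L + d) -= Wj * X.col(w * L + d - a);
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& dY, const arma::mat& W,
                  const arma::mat& X, const int L, const int k,
                  const bool want_dx) {
  const int nc = X.n_cols, cin = X.n_rows;
  const int half = (k - 1) / 2, nwin = nc / L;
  arma::mat dW(W.n_rows, W.n_cols);
  for (int j = 0; j < k; ++j) {
    const int off = j - half;
    arma::mat dWj;
    if (off == 0) {
      dWj = dY * X.t();
    } else if (off > 0) {
      dWj = dY.cols(0, nc - 1 - off) * X.cols(off, nc - 1).t();
      for (int w = 1; w < nwin; ++w)
        for (int d = 1; d <= off; ++d)
          dWj -= dY.col(w * L - d) * X.col(w * L - d + off).t();
    } else {
      const int a = -off;
      dWj = dY.cols(a, nc - 1) * X.cols(0, nc - 1 - a).t();
      for (int w = 1; w < nwin; ++w)
        for (int d = 0; d < a; ++d)
          dWj -= dY.col(w * L + d) * X.col(w * L + d - a).t();
    }
    dW.cols(j * cin, (j + 1) * cin - 1) = dWj;
  }
  arma::vec db = arma::sum(dY, 1);
  if (!want_dx)
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
  arma::mat dX(cin, nc, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = j - half;
    const arma::mat WjT = W.cols(j * cin, (j + 1) * cin - 1).t();
    if (off == 0) {
      dX += WjT * dY;
    } else if (off > 0) {
      // Y[t] used X[t+off]  =>  dX[s] += Wj' dY[s-off]
      dX.cols(off, nc - 1) += WjT * dY.cols(0, nc - 1 - off);
      for (int w = 1; w < nwin; ++w)
        for (int d = 1; d <= off; ++d)
          dX.col(w * L - d + off) -= WjT * dY.col(w * L - d);
    } else {
      const int a = -off;
      dX.cols(0, nc - 1 - a) += WjT * dY.cols(a, nc - 1);
      for (int w = 1; w < nwin; ++w)
        for (int d = 0; d < a; ++d)
          dX.col(w * L + d - a) -= WjT * dY.col(w * L + d);
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// ---- batch normalization (per row) ----

// [[Rcpp::export]]
List bn_fwd_train_cpp(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, const double eps) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat Xc = X.each_col() - mu;
  arma::vec v = arma::mean(arma::square(Xc), 1);
  arma::vec invstd = 1.0 / arma::sqrt(v + eps);
  arma::mat Y = Xc.each_col() % (gamma % invstd);
  Y.each_col() += beta;
  return List::create(_["Y"] = Y, _["mu"] = mu, _["var"] = v,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
arma::mat bn_fwd_eval_cpp(const arma::mat& X, const arma::vec& gamma,
                          const arma::vec& beta, const arma::vec& run_mean,
                          const arma::vec& run_var, const double eps) {
  arma::vec invstd = 1.0 / arma::sqrt(run_var + eps);
  arma::mat Y = (X.each_col() - run_mean).each_col() % (gamma % invstd);
  Y.each_col() += beta;
  return Y;
}

// [[Rcpp::export]]
List bn_bwd_cpp(const arma::mat& dY, const arma::vec& gamma,
                const arma::mat& X, const arma::vec& mu,
                const arma::vec& invstd) {
  const int nr = X.n_rows, nc = X.n_cols;
  arma::vec dgamma(nr, arma::fill::zeros), dbeta(nr, arma::fill::zeros);
  arma::mat dX(nr, nc);
  // per row: xhat = (x - mu) * invstd; dX = invstd * (dxhat
  //   - mean(dxhat) - xhat * mean(dxhat * xhat)), dxhat = dY * gamma;
  // loops run column-major to match storage
  for (int c = 0; c < nc; ++c) {
    const double* xc = X.colptr(c);
    const double* dyc = dY.colptr(c);
    for (int r = 0; r < nr; ++r) {
      const double xh = (xc[r] - mu(r)) * invstd(r);
      dbeta(r) += dyc[r];
      dgamma(r) += dyc[r] * xh;
    }
  }
  arma::vec m_dxh = gamma % dbeta / nc, m_dxhx = gamma % dgamma / nc;
  for (int c = 0; c < nc; ++c) {
    const double* xc = X.colptr(c);
    const double* dyc = dY.colptr(c);
    double* dxc = dX.colptr(c);
    for (int r = 0; r < nr; ++r) {
      const double xh = (xc[r] - mu(r)) * invstd(r);
      dxc[r] = invstd(r) * (gamma(r) * dyc[r] - m_dxh(r) - xh * m_dxhx(r));
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- Softsign ----

// [[Rcpp::export]]
arma::mat softsign_fwd_cpp(const arma::mat& X) {
  return X / (1.0 + arma::abs(X));
}

// [[Rcpp::export]]
arma::mat softsign_bwd_cpp(const arma::mat& dY, const arma::mat& X) {
  arma::mat s = 1.0 + arma::abs(X);
  return dY / (s % s);
}

// ---- temporal max pooling (width p, stride p, remainder dropped) ----

// [[Rcpp::export]]
List pool_fwd_cpp(const arma::mat& X, const int L, const int p) {
  const int nc = X.n_cols, nr = X.n_rows;
  const int nwin = nc / L, Lout = L / p;
  arma::mat Y(nr, Lout * nwin);
  IntegerMatrix arg(nr, Lout * nwin);
  for (int w = 0; w < nwin; ++w)
    for (int t = 0; t < Lout; ++t) {
      const int oc = w * Lout + t, ic0 = w * L + t * p;
      for (int r = 0; r < nr; ++r) {
        double best = X(r, ic0);
        int bj = 0;
        for (int j = 1; j < p; ++j)
          if (X(r, ic0 + j) > best) { best = X(r, ic0 + j); bj = j; }
        Y(r, oc) = best;
        arg(r, oc) = bj;
      }
    }
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::mat pool_bwd_cpp(const arma::mat& dY, const IntegerMatrix& arg,
                       const int L, const int p, const int nc_in) {
  const int nr = dY.n_rows, Lout = L / p, nwin = nc_in / L;
  arma::mat dX(nr, nc_in, arma::fill::zeros);
  for (int w = 0; w < nwin; ++w)
    for (int t = 0; t < Lout; ++t) {
      const int oc = w * Lout + t, ic0 = w * L + t * p;
      for (int r = 0; r < nr; ++r)
        dX(r, ic0 + arg(r, oc)) = dY(r, oc);
    }
  return dX;
}
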