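// 3x3 convolution primitives on (H*W*B) x C feature-map matrices.
// The R side supplies gather indices (one column per kernel offset,
// out-of-bounds pixels pointing one past the last row and read as
// zero), so these kernels are just tight gather + GEMM loops.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void gatherRows(const arma::mat& src, const arma::imat& idx, int k,
                       arma::mat& dst) {
  const int n = idx.n_rows, c = src.n_cols, m = src.n_rows;
  for (int j = 0; j < c; ++j) {
    const double* s = src.colptr(j);
    double* d = dst.colptr(j);
    for (int i = 0; i < n; ++i) {
      const int id = idx(i, k);
      d[i] = (id > m) ? 0.0 : s[id - 1];
    }
  }
}

// [[Rcpp::export(name = ".conv3FwdCpp")]]
arma::mat conv3_fwd_cpp(const arma::mat& X, const arma::imat& idx,
                        const List& W, const arma::vec& b) {
  const int n = idx.n_rows;
  arma::mat W0 = as<arma::mat>(W[0]);
  const int cin = W0.n_rows, cout = W0.n_cols;
  arma::mat Y(n, cout, arma::fill::zeros);
  arma::mat Xs(n, cin);
  for (int k = 0; k < 9; ++k) {
    arma::mat Wk = as<arma::mat>(W[k]);
    gatherRows(X, idx, k, Xs);
    Y += Xs * Wk;
  }
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".conv3BwdCpp")]]
List conv3_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                   const arma::imat& idx, const List& W) {
  const int n = idx.n_rows;
  arma::mat W0 = as<arma::mat>(W[0]);
  const int cin = W0.n_rows, cout = W0.n_cols;
  arma::mat dX(n, cin, arma::fill::zeros);
  arma::mat Xs(n, cin), dYs(n, cout);
  List dW(9);
  for (int k = 0; k < 9; ++k) {
    arma::mat Wk = as<arma::mat>(W[k]);
    gatherRows(X, idx, k, Xs);
    dW[k] = wrap(arma::mat(Xs.t() * dY));
    gatherRows(dY, idx, 8 - k, dYs);    // transposed (flipped) offset
    dX += dYs * Wk.t();
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dW"] = dW,
                      _["db"] = arma::vec(db.t()));
}

// Strided (stride-2) backward: idx gathers full-resolution input rows
// for each low-resolution output row, so the input gradient is a
// scatter-add over the same indices.
// [[Rcpp::export(name = ".conv3BwdStrideCpp")]]
List conv3_bwd_stride_cpp(const arma::mat& dY, const arma::mat& X,
                          const arma::imat& idx, const List& W) {
  const int n = idx.n_rows;       // low-res rows
  const int m = X.n_rows;         // full-res rows
  arma::mat W0 = as<arma::mat>(W[0]);
  const int cin = W0.n_rows;
  arma::mat dX(m, cin, arma::fill::zeros);
  arma::mat Xs(n, cin), dYW(n, cin);
  List dW(9);
  for (int k = 0; k < 9; ++k) {
    arma::mat Wk = as<arma::mat>(W[k]);
    gatherRows(X, idx, k, Xs);
    dW[k] = wrap(arma::mat(Xs.t() * dY));
    dYW = dY * Wk.t();
    for (int j = 0; j < cin; ++j) {
      double* d = dX.colptr(j);
      const double* s = dYW.colptr(j);
      for (int i = 0; i < n; ++i) {
        const int id = idx(i, k);
        if (id <= m) d[id - 1] += s[i];
      }
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dW"] = dW,
                      _["db"] = arma::vec(db.t()));
}
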