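// Zero-padded dilated 2D convolution kernels for the direct-inference
// network.  Activations are (pixels*batch) x channels matrices; the patch
// geometry is precomputed in R as a source-row map D (pixels*batch x k^2,
// 1-based row in the activation matrix, 0 for padding), so both the im2col
// expansion and its transpose are plain indexed copies and the heavy
// lifting is a single BLAS gemm per layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void fill_im2col(arma::mat& xcol, const arma::mat& A,
                        const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cin = A.n_cols;
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cin; ++c) {
      double* dst = xcol.colptr(o * cin + c);
      const double* ac = A.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        dst[i] = s ? ac[s - 1] : 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& A, const arma::mat& W,
                       const arma::vec& b, const IntegerMatrix& D) {
  const int n = D.nrow();
  arma::mat xcol(n, W.n_rows);
  fill_im2col(xcol, A, D);
  arma::mat Y = xcol * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& A, const arma::mat& dY,
                  const arma::mat& W, const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cin = A.n_cols;
  arma::mat xcol(n, W.n_rows);
  fill_im2col(xcol, A, D);
  arma::mat dW = xcol.t() * dY;
  arma::mat dxcol = dY * W.t();
  arma::mat dA(n, cin, arma::fill::zeros);
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cin; ++c) {
      const double* g = dxcol.colptr(o * cin + c);
      double* ac = dA.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        if (s) ac[s - 1] += g[i];
      }
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(Named("dA") = dA, Named("dW") = dW,
                      Named("db") = arma::vec(db.t()));
}

// Depthwise convolution: one k x k filter per channel (w is k^2 x C).
// [[Rcpp::export]]
arma::mat dwconv_fwd_cpp(const arma::mat& A, const arma::mat& w,
                         const arma::vec& b, const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cc = A.n_cols;
  arma::mat Y(n, cc);
  Y.each_row() = b.t();
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cc; ++c) {
      const double wv = w(o, c);
      const double* ac = A.colptr(c);
      double* yc = Y.colptr(c);
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        if (s) yc[i] += wv * ac[s - 1];
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const arma::mat& A, const arma::mat& dY,
                    const arma::mat& w, const IntegerMatrix& D) {
  const int n = D.nrow(), k2 = D.ncol(), cc = A.n_cols;
  arma::mat dw(k2, cc, arma::fill::zeros);
  arma::mat dA(n, cc, arma::fill::zeros);
  for (int o = 0; o < k2; ++o) {
    const int* src = &D(0, o);
    for (int c = 0; c < cc; ++c) {
      const double wv = w(o, c);
      const double* ac = A.colptr(c);
      const double* gc = dY.colptr(c);
      double* dac = dA.colptr(c);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const int s = src[i];
        if (s) {
          acc += ac[s - 1] * gc[i];
          dac[s - 1] += wv * gc[i];
        }
      }
      dw(o, c) = acc;
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(Named("dA") = dA, Named("dw") = dw,
                      Named("db") = arma::vec(db.t()));
}
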