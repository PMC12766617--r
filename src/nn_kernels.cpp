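// Hot inner kernels of the de-noising networks: im2col gather / col2im
// scatter for convolutions, and batched non-overlapping window attention.
// The surrounding forward/backward logic (and all gradient mathematics)
// lives in R; these kernels only remove interpreter overhead from tight
// loops and are covered by the same finite-difference gradient checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather: col[i, j] = xp[idx[i, j] - 1]
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& xp, const IntegerMatrix& idx) {
  const int np = idx.nrow(), nc = idx.ncol();
  NumericMatrix col(np, nc);
  const double* px = xp.begin();
  const int* pi = idx.begin();
  double* pc = col.begin();
  const R_xlen_t n = (R_xlen_t)np * nc;
  for (R_xlen_t k = 0; k < n; ++k) pc[k] = px[pi[k] - 1];
  return col;
}

// scatter-add: dxp[idx[i, j] - 1] += dcol[i, j]
// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& dcol, const IntegerMatrix& idx,
                         int n_out) {
  const int np = idx.nrow(), nc = idx.ncol();
  NumericVector dxp(n_out);
  const double* pd = dcol.begin();
  const int* pi = idx.begin();
  double* po = dxp.begin();
  const R_xlen_t n = (R_xlen_t)np * nc;
  for (R_xlen_t k = 0; k < n; ++k) po[pi[k] - 1] += pd[k];
  return dxp;
}

// Batched softmax attention over contiguous T-row window blocks.
// qkv_w: (nw*T) x 3C with [Q | K | V] column blocks, head slices of width
// dh = C/heads inside each block. Returns the attention output om_w
// ((nw*T) x C) and the row-softmax probabilities P for every window/head
// ((nw*T) x (T*heads)) for the backward pass.
// [[Rcpp::export]]
List attn_fwd_cpp(const arma::mat& qkv_w, int T, int heads, double scl) {
  const int C = qkv_w.n_cols / 3;
  const int dh = C / heads;
  const int nw = qkv_w.n_rows / T;
  arma::mat om(qkv_w.n_rows, C, arma::fill::zeros);
  arma::mat P_all(qkv_w.n_rows, T * heads, arma::fill::zeros);
  for (int w = 0; w < nw; ++w) {
    const arma::uword r0 = (arma::uword)w * T, r1 = r0 + T - 1;
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat Q = qkv_w.submat(r0, c0, r1, c1);
      arma::mat K = qkv_w.submat(r0, C + c0, r1, C + c1);
      arma::mat V = qkv_w.submat(r0, 2 * C + c0, r1, 2 * C + c1);
      arma::mat S = Q * K.t() * scl;
      S.each_col() -= arma::max(S, 1);
      arma::mat E = arma::exp(S);
      arma::vec rs = arma::sum(E, 1);
      E.each_col() /= rs;
      om.submat(r0, c0, r1, c1) = E * V;
      P_all.submat(r0, (arma::uword)h * T, r1, (arma::uword)(h + 1) * T - 1) = E;
    }
  }
  return List::create(Named("om") = om, Named("P") = P_all);
}

// Backward of the batched window attention: given upstream gradients on the
// attention output (dom_w), the cached qkv_w and probabilities P, returns
// the gradient with respect to qkv_w.
// [[Rcpp::export]]
arma::mat attn_bwd_cpp(const arma::mat& dom_w, const arma::mat& qkv_w,
                       const arma::mat& P_all, int T, int heads, double scl) {
  const int C = qkv_w.n_cols / 3;
  const int dh = C / heads;
  const int nw = qkv_w.n_rows / T;
  arma::mat dqkv(qkv_w.n_rows, 3 * C, arma::fill::zeros);
  for (int w = 0; w < nw; ++w) {
    const arma::uword r0 = (arma::uword)w * T, r1 = r0 + T - 1;
    for (int h = 0; h < heads; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat Q = qkv_w.submat(r0, c0, r1, c1);
      arma::mat K = qkv_w.submat(r0, C + c0, r1, C + c1);
      arma::mat V = qkv_w.submat(r0, 2 * C + c0, r1, 2 * C + c1);
      arma::mat P = P_all.submat(r0, (arma::uword)h * T, r1,
                                 (arma::uword)(h + 1) * T - 1);
      arma::mat dO = dom_w.submat(r0, c0, r1, c1);
      arma::mat dV = P.t() * dO;
      arma::mat dP = dO * V.t();
      arma::vec rowdot = arma::sum(dP % P, 1);
      arma::mat dS = P % (dP.each_col() - rowdot);
      dqkv.submat(r0, c0, r1, c1) = dS * K * scl;
      dqkv.submat(r0, C + c0, r1, C + c1) = dS.t() * Q * scl;
      dqkv.submat(r0, 2 * C + c0, r1, 2 * C + c1) = dV;
    }
  }
  return dqkv;
}
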