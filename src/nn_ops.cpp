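// Inner kernels of the sequence CNN: same-padding 1-D convolution
// (im2col + GEMM) and non-overlapping max-pooling, both on the package's
// b-major layout: row (b-1)*L + l of X holds position l of sequence b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// gather X (B*L x Cin) into the im2col matrix (B*L x k*Cin), zero padding
static mat im2col(const mat& X, int B, int L, int k) {
  const int Cin = X.n_cols;
  const int p = (k - 1) / 2;
  mat out(B * L, k * Cin, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int shift = o - p;              // source position l + shift
    const int lo = std::max(0, -shift);   // first valid output position
    const int hi = std::min(L, L - shift) - 1;
    if (hi < lo) continue;
    for (int b = 0; b < B; ++b) {
      const int dst0 = b * L + lo;
      const int src0 = b * L + lo + shift;
      out.submat(dst0, o * Cin, dst0 + (hi - lo), (o + 1) * Cin - 1) =
        X.rows(src0, src0 + (hi - lo));
    }
  }
  return out;
}

// scatter-add the im2col gradient back onto the input layout
static mat col2im(const mat& dXcol, int B, int L, int k, int Cin) {
  const int p = (k - 1) / 2;
  mat dX(B * L, Cin, fill::zeros);
  for (int o = 0; o < k; ++o) {
    const int shift = o - p;
    const int lo = std::max(0, -shift);
    const int hi = std::min(L, L - shift) - 1;
    if (hi < lo) continue;
    for (int b = 0; b < B; ++b) {
      const int dst0 = b * L + lo + shift;
      const int src0 = b * L + lo;
      dX.rows(dst0, dst0 + (hi - lo)) +=
        dXcol.submat(src0, o * Cin, src0 + (hi - lo), (o + 1) * Cin - 1);
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& X, int B, int L, int k,
                         const arma::mat& W, const arma::vec& bias) {
  mat Y = im2col(X, B, L, k) * W;
  Y.each_row() += bias.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::mat& X, int B, int L, int k,
                          const arma::mat& W, const arma::mat& dY) {
  mat Xcol = im2col(X, B, L, k);
  mat dW = Xcol.t() * dY;
  rowvec db = sum(dY, 0);
  mat dXcol = dY * W.t();
  mat dX = col2im(dXcol, B, L, k, X.n_cols);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db.t());
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::mat& X, int B, int L, int p) {
  const int C = X.n_cols, L2 = L / p;
  mat Y(B * L2, C);
  imat chosen(B * L2, C);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < L2; ++j) {
      const int out_r = b * L2 + j;
      const int in_r0 = b * L + j * p;
      for (int c = 0; c < C; ++c) {
        double best = X(in_r0, c);
        int arg = 0;
        for (int s = 1; s < p; ++s)
          if (X(in_r0 + s, c) > best) { best = X(in_r0 + s, c); arg = s; }
        Y(out_r, c) = best;
        chosen(out_r, c) = arg;
      }
    }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("chosen") = chosen);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::imat& chosen, const arma::mat& dY,
                          int B, int L, int p) {
  const int C = dY.n_cols, L2 = L / p;
  mat dX(B * L, C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < L2; ++j) {
      const int out_r = b * L2 + j;
      const int in_r0 = b * L + j * p;
      for (int c = 0; c < C; ++c)
        dX(in_r0 + chosen(out_r, c), c) += dY(out_r, c);
    }
  return dX;
}
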