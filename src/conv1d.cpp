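// Compiled kernels for the 1-D convolutional layers: im2col + GEMM forward,
// gradient accumulation and col2im backward, and non-overlapping max pooling.
// Shapes follow the R side: input batches are (L, C, B) cubes, convolution
// activations (B*Lout) x F matrices with row index (b-1)*Lout + t, weights
// (k*C) x F with row order (c-1)*k + j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void im2col_sample(const cube& X, int b, int k, int Lout, mat& M) {
  const int C = X.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* src = X.slice_colptr(b, c);
    for (int j = 0; j < k; ++j) {
      std::memcpy(M.colptr(c * k + j), src + j, Lout * sizeof(double));
    }
  }
}

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::cube& X, const arma::mat& W,
                     const arma::vec& bias, int k) {
  const int L = X.n_rows, B = X.n_slices, F = W.n_cols;
  const int Lout = L - k + 1;
  mat Z(B * Lout, F);
  mat M(Lout, W.n_rows);
  for (int b = 0; b < B; ++b) {
    im2col_sample(X, b, k, Lout, M);
    Z.rows(b * Lout, (b + 1) * Lout - 1) = M * W;
  }
  Z.each_row() += bias.t();
  return Z;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::mat& W,
                      const arma::mat& dZ, int k, bool need_dx) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const int F = W.n_cols;
  const int Lout = L - k + 1;
  mat dW(W.n_rows, F, fill::zeros);
  mat M(Lout, W.n_rows);
  cube dX;
  if (need_dx) dX.zeros(L, C, B);
  for (int b = 0; b < B; ++b) {
    im2col_sample(X, b, k, Lout, M);
    const mat dZb = dZ.rows(b * Lout, (b + 1) * Lout - 1);
    dW += M.t() * dZb;
    if (need_dx) {
      mat dM = dZb * W.t();
      for (int c = 0; c < C; ++c) {
        double* dst = dX.slice_colptr(b, c);
        for (int j = 0; j < k; ++j) {
          const double* src = dM.colptr(c * k + j);
          for (int t = 0; t < Lout; ++t) dst[t + j] += src[t];
        }
      }
    }
  }
  vec db = sum(dZ, 0).t();
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) out["dX"] = dX;
  return out;
}

// Max pooling of A ((B*Lout) x F, row (b-1)*Lout + t) with non-overlapping
// window p.  Returns pooled values as an (Lp, B, F) cube and 1-based flat
// argmax indices into the (Lout, B, F) layout.
// [[Rcpp::export]]
Rcpp::List pool1d_fwd(const arma::mat& A, int Lout, int B, int p) {
  const int F = A.n_cols;
  const int Lp = Lout / p;
  cube P(Lp, B, F);
  Rcpp::IntegerVector argmax(Lp * B * F);
  int n = 0;
  for (int f = 0; f < F; ++f) {
    const double* col = A.colptr(f);
    for (int b = 0; b < B; ++b) {
      const double* s = col + b * Lout;
      for (int lp = 0; lp < Lp; ++lp) {
        int t0 = lp * p;
        int best = t0;
        double v = s[t0];
        for (int t = t0 + 1; t < t0 + p; ++t) {
          if (s[t] > v) { v = s[t]; best = t; }
        }
        P(lp, b, f) = v;
        argmax[n++] = best + 1 + Lout * (b + B * f);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("P") = P,
                            Rcpp::Named("argmax") = argmax);
}
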