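// 1-D convolution primitives for the denoising autoencoder.
// Activations are cubes of shape (channels, length, samples); weights are
// (out_channels x in_channels*kernel) so the convolution reduces to an
// im2col matrix product handled by BLAS. Samples are processed in chunks
// large enough for efficient gemm but bounded in scratch memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int CHUNK = 32; // samples per im2col block

// column-ised receptive fields of samples [s0, s1): (Cin*k) x (L*(s1-s0))
static void im2col_chunk(const cube &X, int k, int s0, int s1, mat &out) {
  const int C = X.n_rows, L = X.n_cols, pad = k / 2, ns = s1 - s0;
  out.zeros(C * k, L * ns);
  for (int s = 0; s < ns; ++s) {
    const mat &x = X.slice(s0 + s);
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      const int lo = std::max(0, -off), hi = std::min(L, L - off);
      if (lo >= hi) continue;
      out.submat(j * C, s * L + lo, (j + 1) * C - 1, s * L + hi - 1) =
          x.cols(lo + off, hi - 1 + off);
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_forward(const arma::cube &X, const arma::mat &W,
                          const arma::vec &b, int k) {
  const int L = X.n_cols, N = X.n_slices, Cout = W.n_rows;
  cube Y(Cout, L, N);
  mat col;
  for (int s0 = 0; s0 < N; s0 += CHUNK) {
    const int s1 = std::min(N, s0 + CHUNK), ns = s1 - s0;
    im2col_chunk(X, k, s0, s1, col);
    mat out = W * col; // Cout x (L*ns)
    out.each_col() += b;
    for (int s = 0; s < ns; ++s)
      Y.slice(s0 + s) = out.cols(s * L, (s + 1) * L - 1);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::cube &X, const arma::mat &W,
                           const arma::cube &dY, int k) {
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices;
  const int pad = k / 2;
  cube dX(C, L, N, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  mat col, dy, dcol;
  for (int s0 = 0; s0 < N; s0 += CHUNK) {
    const int s1 = std::min(N, s0 + CHUNK), ns = s1 - s0;
    im2col_chunk(X, k, s0, s1, col);
    dy.set_size(W.n_rows, L * ns);
    for (int s = 0; s < ns; ++s)
      dy.cols(s * L, (s + 1) * L - 1) = dY.slice(s0 + s);
    dW += dy * col.t();
    db += sum(dy, 1);
    dcol = W.t() * dy; // (C*k) x (L*ns)
    // col2im: scatter-add receptive-field gradients back onto positions
    for (int s = 0; s < ns; ++s) {
      mat &dxs = dX.slice(s0 + s);
      for (int j = 0; j < k; ++j) {
        const int off = j - pad;
        const int lo = std::max(0, -off), hi = std::min(L, L - off);
        if (lo >= hi) continue;
        dxs.cols(lo + off, hi - 1 + off) +=
            dcol.submat(j * C, s * L + lo, (j + 1) * C - 1, s * L + hi - 1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// fused in-place ReLU (returns mask-free copy)
// [[Rcpp::export]]
arma::cube relu_cpp(const arma::cube &X) {
  cube Y = X;
  Y.for_each([](double &v) { if (v < 0) v = 0; });
  return Y;
}

// Manhattan distance matrix between rows of a (n x p) and rows of b (m x p).
// [[Rcpp::export]]
arma::mat manhattan_dist_cpp(const arma::mat &a, const arma::mat &b) {
  const int n = a.n_rows, m = b.n_rows;
  mat D(n, m);
  for (int j = 0; j < m; ++j) {
    rowvec bj = b.row(j);
    for (int i = 0; i < n; ++i)
      D(i, j) = accu(abs(a.row(i) - bj));
  }
  return D;
}

// LayerNorm over channels at each (position, sample), per-channel affine.
// [[Rcpp::export]]
Rcpp::List layernorm_forward(const arma::cube &X, const arma::vec &gamma,
                             const arma::vec &beta, double eps) {
  const int L = X.n_cols, N = X.n_slices;
  cube xhat(arma::size(X)), Y(arma::size(X));
  mat inv(L, N);
  for (int s = 0; s < N; ++s) {
    rowvec mu = mean(X.slice(s), 0);
    mat xc = X.slice(s).each_row() - mu;
    rowvec v = mean(square(xc), 0);
    rowvec iv = 1.0 / sqrt(v + eps);
    xhat.slice(s) = xc.each_row() % iv;
    mat ys = xhat.slice(s).each_col() % gamma;
    ys.each_col() += beta;
    Y.slice(s) = ys;
    inv.col(s) = iv.t();
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layernorm_backward(const arma::cube &dY, const arma::cube &xhat,
                              const arma::mat &inv, const arma::vec &gamma) {
  const int N = dY.n_slices;
  cube dX(arma::size(dY));
  vec dgamma(gamma.n_elem, fill::zeros), dbeta(gamma.n_elem, fill::zeros);
  for (int s = 0; s < N; ++s) {
    const mat &xh = xhat.slice(s);
    dgamma += sum(dY.slice(s) % xh, 1);
    dbeta += sum(dY.slice(s), 1);
    mat dxhat = dY.slice(s).each_col() % gamma;
    rowvec m1 = mean(dxhat, 0);
    rowvec m2 = mean(dxhat % xh, 0);
    mat tmp = dxhat.each_row() - m1;
    tmp -= xh.each_row() % m2;
    dX.slice(s) = tmp.each_row() % inv.col(s).t();
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
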