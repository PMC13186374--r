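// Low-level numeric kernels for the 1-D residual network and the
// polyphase resampler. Activations are cubes laid out (length, channels,
// batch); convolution weights are (out_channels x kernel*in_channels)
// with column index k + K*c, biases are plain vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for one batch slice with zero "same" padding; K must be odd.
static void fill_patches(const mat& Xs, int K, mat& G) {
  const int L = Xs.n_rows, C = Xs.n_cols, pad = (K - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const int r = k + K * c;
      for (int l = 0; l < L; ++l) {
        const int t = l + k - pad;
        G(r, l) = (t >= 0 && t < L) ? Xs(t, c) : 0.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv1dForward")]]
arma::cube conv1d_forward(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows, K = W.n_cols / Cin;
  if (K % 2 == 0) Rcpp::stop("kernel size must be odd");
  cube Y(L, Cout, B);
  mat G(K * Cin, L);
  for (int s = 0; s < B; ++s) {
    fill_patches(X.slice(s), K, G);
    mat Ys = W * G;          // Cout x L
    Ys.each_col() += b;
    Y.slice(s) = Ys.t();
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1dBackward")]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::mat& W,
                           const arma::cube& dY) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows, K = W.n_cols / Cin, pad = (K - 1) / 2;
  cube dX(L, Cin, B, fill::zeros);
  mat dW(Cout, K * Cin, fill::zeros);
  vec db(Cout, fill::zeros);
  mat G(K * Cin, L);
  for (int s = 0; s < B; ++s) {
    fill_patches(X.slice(s), K, G);
    mat dYs = dY.slice(s).t();       // Cout x L
    dW += dYs * G.t();
    db += sum(dYs, 1);
    mat dG = W.t() * dYs;            // K*Cin x L
    mat& dXs = dX.slice(s);
    for (int c = 0; c < Cin; ++c) {
      for (int k = 0; k < K; ++k) {
        const int r = k + K * c;
        for (int l = 0; l < L; ++l) {
          const int t = l + k - pad;
          if (t >= 0 && t < L) dXs(t, c) += dG(r, l);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".avgPoolForward")]]
arma::cube avgpool_forward(const arma::cube& X, int stride) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const int Lo = L / stride;
  cube Y(Lo, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < Lo; ++l) {
        double acc = 0.0;
        for (int j = 0; j < stride; ++j) acc += X(l * stride + j, c, s);
        Y(l, c, s) = acc / stride;
      }
  return Y;
}

// [[Rcpp::export(name = ".avgPoolBackward")]]
arma::cube avgpool_backward(const arma::cube& dY, int stride, int L) {
  const int Lo = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(L, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < Lo; ++l) {
        const double g = dY(l, c, s) / stride;
        for (int j = 0; j < stride; ++j) dX(l * stride + j, c, s) += g;
      }
  return dX;
}

// Rational polyphase FIR resampler: conceptually upsample by p
// (zero-stuffing, gain p), filter with h (odd length, linear phase,
// group delay (len(h)-1)/2 compensated), keep every q-th sample.
// [[Rcpp::export(name = ".firResample")]]
arma::vec fir_resample(const arma::vec& x, const arma::vec& h,
                       int p, int q) {
  const int n = x.n_elem, nt = h.n_elem;
  if (nt % 2 == 0) Rcpp::stop("filter length must be odd");
  const int D = (nt - 1) / 2;
  const int n_out = (int)std::floor((double)n * p / q);
  vec y(n_out, fill::zeros);
  for (int m = 0; m < n_out; ++m) {
    const long long u = (long long)m * q + D;   // high-rate tap centre
    // x[j] contributes through h[u - p*j]
    long long j_lo = (u - (nt - 1) + p - 1) / p;  // ceil((u-nt+1)/p)
    if (u < (long long)(nt - 1)) j_lo = 0;
    long long j_hi = u / p;
    if (j_hi > n - 1) j_hi = n - 1;
    double acc = 0.0;
    for (long long j = j_lo; j <= j_hi; ++j) acc += x(j) * h(u - p * j);
    y(m) = acc * p;
  }
  return y;
}
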