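// Convolution primitives for the three-layer super-resolution network.
//
// Weight layout convention (shared with the R side): a layer mapping Cin -> Cout
// channels with a k x k kernel is stored as a (k*k*Cin) x Cout matrix whose row
// index is ki + k*kj + k*k*c (0-based), where ki/kj are the kernel row/column
// offsets and c the input channel. "Same" padding with zero fill; k must be odd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  mat cols(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    mat xp(H + 2 * pad, W + 2 * pad, fill::zeros);
    xp.submat(pad, pad, pad + H - 1, pad + W - 1) = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        cols.col(ki + k * kj + k * k * c) =
          vectorise(xp.submat(ki, kj, ki + H - 1, kj + W - 1));
      }
    }
  }
  return cols;
}

// Forward 2-D convolution (cross-correlation, as in deep-learning use), same
// padding. x: H x W x Cin, w: (k*k*Cin) x Cout, bias: Cout.
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& bias, const int k) {
  if (k < 1 || k % 2 == 0) Rcpp::stop("kernel size must be odd and positive");
  if ((int)w.n_rows != k * k * (int)x.n_slices)
    Rcpp::stop("weight rows do not match k*k*Cin");
  if (w.n_cols != bias.n_elem) Rcpp::stop("bias length does not match Cout");
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y = im2col_same(x, k) * w;
  y.each_row() += bias.t();
  cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = reshape(y.col(o), H, W);
  return out;
}

// Weight gradient of the same-padded convolution: dW = im2col(x)^T * dy.
// x: H x W x Cin, dy: H x W x Cout -> (k*k*Cin) x Cout.
// [[Rcpp::export]]
arma::mat cpp_conv2d_gradw(const arma::cube& x, const arma::cube& dy,
                           const int k) {
  if (k < 1 || k % 2 == 0) Rcpp::stop("kernel size must be odd and positive");
  if (x.n_rows != dy.n_rows || x.n_cols != dy.n_cols)
    Rcpp::stop("x and dy spatial shapes differ");
  const int HW = x.n_rows * x.n_cols, Cout = dy.n_slices;
  mat dyf(HW, Cout);
  for (int o = 0; o < Cout; ++o)
    dyf.col(o) = vectorise(dy.slice(o));
  return im2col_same(x, k).t() * dyf;
}
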