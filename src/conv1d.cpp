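// 1-D convolution layers via im2col + GEMM, the workhorse of the
// pooling-free AlexNet variant. Batch layout: cube (length, channels,
// batch); weights: (out_ch) x (in_ch * k) with kernel position varying
// fastest within a channel block.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::mat& x, const int k, const int stride,
                        const int out_len) {
  const int in_ch = x.n_cols;
  arma::mat K(out_len, in_ch * k);
  for (int ic = 0; ic < in_ch; ++ic)
    for (int kk = 0; kk < k; ++kk)
      for (int t = 0; t < out_len; ++t)
        K(t, ic * k + kk) = x(t * stride + kk, ic);
  return K;
}

// [[Rcpp::export(name = ".conv1d_forward_cpp")]]
arma::cube conv1d_forward_cpp(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, const int k,
                              const int stride) {
  const int len = x.n_rows, batch = x.n_slices, out_ch = w.n_rows;
  const int out_len = (len - k) / stride + 1;
  if (out_len < 1) stop("input shorter than kernel");
  arma::cube y(out_len, out_ch, batch);
  for (int s = 0; s < batch; ++s) {
    arma::mat K = im2col(x.slice(s), k, stride, out_len);
    y.slice(s) = K * w.t();
    y.slice(s).each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_backward_cpp")]]
List conv1d_backward_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::cube& dy, const int k,
                         const int stride) {
  const int batch = x.n_slices, out_len = dy.n_rows;
  const int in_ch = x.n_cols;
  arma::cube dx(x.n_rows, x.n_cols, batch, arma::fill::zeros);
  arma::mat dw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::vec db(w.n_rows, arma::fill::zeros);
  for (int s = 0; s < batch; ++s) {
    arma::mat K = im2col(x.slice(s), k, stride, out_len);
    const arma::mat& g = dy.slice(s);
    dw += g.t() * K;
    db += arma::sum(g, 0).t();
    arma::mat dK = g * w;  // out_len x (in_ch * k)
    arma::mat& dxs = dx.slice(s);
    for (int ic = 0; ic < in_ch; ++ic)
      for (int kk = 0; kk < k; ++kk)
        for (int t = 0; t < out_len; ++t)
          dxs(t * stride + kk, ic) += dK(t, ic * k + kk);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
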