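// Hot-loop kernels for the neural-network trainers: per-channel batch
// normalization on (length, channel, batch) cubes, ReLU, and the Adam
// parameter update. Kept in C++ because the per-batch R-level array
// copies dominated training time.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".bn1d_forward_cpp")]]
List bn1d_forward_cpp(const arma::cube& z, const arma::vec& gamma,
                      const arma::vec& beta, const double eps) {
  const int L = z.n_rows, C = z.n_cols, B = z.n_slices;
  const double n = (double)L * B;
  arma::vec mu(C, arma::fill::zeros), va(C, arma::fill::zeros);
  for (int s = 0; s < B; ++s) mu += arma::sum(z.slice(s), 0).t();
  mu /= n;
  for (int s = 0; s < B; ++s) {
    arma::mat d = z.slice(s);
    d.each_row() -= mu.t();
    va += arma::sum(arma::square(d), 0).t();
  }
  va /= n;
  arma::vec istd = 1.0 / arma::sqrt(va + eps);
  arma::cube y(L, C, B);
  for (int s = 0; s < B; ++s) {
    arma::mat d = z.slice(s);
    d.each_row() -= mu.t();
    d.each_row() %= (istd % gamma).t();
    d.each_row() += beta.t();
    y.slice(s) = d;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["va"] = va,
                      _["istd"] = istd);
}

// [[Rcpp::export(name = ".bn1d_eval_cpp")]]
arma::cube bn1d_eval_cpp(const arma::cube& z, const arma::vec& gamma,
                         const arma::vec& beta, const arma::vec& mu,
                         const arma::vec& va, const double eps) {
  arma::vec istd = 1.0 / arma::sqrt(va + eps);
  arma::cube y(z.n_rows, z.n_cols, z.n_slices);
  for (arma::uword s = 0; s < z.n_slices; ++s) {
    arma::mat d = z.slice(s);
    d.each_row() -= mu.t();
    d.each_row() %= (istd % gamma).t();
    d.each_row() += beta.t();
    y.slice(s) = d;
  }
  return y;
}

// [[Rcpp::export(name = ".bn1d_backward_cpp")]]
List bn1d_backward_cpp(const arma::cube& dy, const arma::cube& z,
                       const arma::vec& mu, const arma::vec& istd,
                       const arma::vec& gamma) {
  const int L = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  const double n = (double)L * B;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  arma::vec s_dxhat(C, arma::fill::zeros), s_dxhat_xhat(C,
                                                        arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    arma::mat xhat = z.slice(s);
    xhat.each_row() -= mu.t();
    xhat.each_row() %= istd.t();
    const arma::mat& g = dy.slice(s);
    dgamma += arma::sum(g % xhat, 0).t();
    dbeta += arma::sum(g, 0).t();
    arma::mat dxhat = g;
    dxhat.each_row() %= gamma.t();
    s_dxhat += arma::sum(dxhat, 0).t();
    s_dxhat_xhat += arma::sum(dxhat % xhat, 0).t();
  }
  arma::cube dx(L, C, B);
  for (int s = 0; s < B; ++s) {
    arma::mat xhat = z.slice(s);
    xhat.each_row() -= mu.t();
    xhat.each_row() %= istd.t();
    arma::mat dxhat = dy.slice(s);
    dxhat.each_row() %= gamma.t();
    xhat.each_row() %= (s_dxhat_xhat / n).t();
    dxhat -= xhat;
    dxhat.each_row() -= (s_dxhat / n).t();
    dxhat.each_row() %= istd.t();
    dx.slice(s) = dxhat;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_cpp")]]
arma::cube relu_cpp(const arma::cube& x) {
  arma::cube y = x;
  y.elem(arma::find(y < 0)).zeros();
  return y;
}

// Mask dy by the ReLU activity of the forward output a (dy where a > 0).
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
arma::cube relu_bwd_cpp(const arma::cube& dy, const arma::cube& a) {
  arma::cube dx = dy;
  dx.elem(arma::find(a <= 0)).zeros();
  return dx;
}

// One Adam step for a single parameter array (treated as a flat
// vector): returns the updated parameter and moment estimates.
// [[Rcpp::export(name = ".adam_update_cpp")]]
List adam_update_cpp(const arma::vec& p, const arma::vec& m,
                     const arma::vec& v, const arma::vec& g,
                     const int t, const double lr, const double beta1,
                     const double beta2, const double eps) {
  arma::vec m2 = beta1 * m + (1 - beta1) * g;
  arma::vec v2 = beta2 * v + (1 - beta2) * (g % g);
  const double bc1 = 1 - std::pow(beta1, t);
  const double bc2 = 1 - std::pow(beta2, t);
  arma::vec p2 = p - lr * (m2 / bc1) / (arma::sqrt(v2 / bc2) + eps);
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
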