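#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Shared Adam machinery for one optimization block. Moments are local to the
// block (fresh optimizer per block, by design). After every step the iterate
// is clipped to [0,1] and frozen entries (free_mask == 0) are restored from
// frozen_vals, so frozen columns stay at zero and known rows stay bit-exact.

static inline void adam_update(mat& R, mat& m, mat& v, const mat& G,
                               double eta, double beta1, double beta2,
                               double eps, double& b1t, double& b2t,
                               const mat& free_mask, const mat& frozen_vals) {
  m = beta1 * m + (1.0 - beta1) * G;
  v = beta2 * v + (1.0 - beta2) * square(G);
  b1t *= beta1;
  b2t *= beta2;
  R -= eta * (m / (1.0 - b1t)) / (sqrt(v / (1.0 - b2t)) + eps);
  R = clamp(R, 0.0, 1.0);
  R = free_mask % R + (1.0 - free_mask) % frozen_vals;
}

// e1-block: minimize || R'R/N - C ||_F^2; gradient (4/N) R (R'R/N - C)
// [[Rcpp::export(name = ".adam_block_corr")]]
arma::mat adam_block_corr(arma::mat R, const arma::mat& C, int steps,
                          double eta, double beta1, double beta2, double eps,
                          const arma::mat& free_mask,
                          const arma::mat& frozen_vals) {
  const double n = static_cast<double>(R.n_rows);
  mat m(size(R), fill::zeros), v(size(R), fill::zeros);
  double b1t = 1.0, b2t = 1.0;
  for (int t = 0; t < steps; ++t) {
    mat D = R.t() * R / n - C;
    mat G = (4.0 / n) * (R * D);
    adam_update(R, m, v, G, eta, beta1, beta2, eps, b1t, b2t,
                free_mask, frozen_vals);
  }
  if (!R.is_finite()) Rcpp::stop("non-finite iterate in correlation block");
  return R;
}

// e2-block: minimize mean_j (f_j - colmean_j(R))^2;
// gradient wrt R(i,j) is 2 (colmean_j - f_j) / (N * M)
// [[Rcpp::export(name = ".adam_block_freq")]]
arma::mat adam_block_freq(arma::mat R, const arma::rowvec& f, int steps,
                          double eta, double beta1, double beta2, double eps,
                          const arma::mat& free_mask,
                          const arma::mat& frozen_vals) {
  const double n = static_cast<double>(R.n_rows);
  const double mm = static_cast<double>(R.n_cols);
  mat m(size(R), fill::zeros), v(size(R), fill::zeros);
  double b1t = 1.0, b2t = 1.0;
  for (int t = 0; t < steps; ++t) {
    rowvec g = 2.0 * (mean(R, 0) - f) / (n * mm);
    mat G = repmat(g, R.n_rows, 1);
    adam_update(R, m, v, G, eta, beta1, beta2, eps, b1t, b2t,
                free_mask, frozen_vals);
  }
  if (!R.is_finite()) Rcpp::stop("non-finite iterate in frequency block");
  return R;
}
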