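// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Gaussian-process negative log-likelihood for stationary kernels of the form
//   K(tau) = sigma * exp(-alpha * tau) * cos(beta * tau)     (beta = 0 -> OU)
// with iid observation noise of variance sigma_n on the diagonal.  `D` holds
// pairwise |t_i - t_j| (or squared differences for a squared-exponential call
// with alpha = 1/(2 l^2)).  Returns
//   0.5 log|K*| + 0.5 y' K*^-1 y + (n/2) log(2 pi),
// i.e. minus the marginal log-likelihood; a large penalty is returned when the
// Cholesky factorisation fails so optimisers back away from bad regions.

static double nll_from_chol(const arma::mat& K, const arma::vec& y) {
  arma::mat L;
  if (!arma::chol(L, K, "lower")) return 1e10;
  arma::vec v = arma::solve(arma::trimatl(L), y);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return 0.5 * logdet + 0.5 * arma::dot(v, v) +
         0.5 * static_cast<double>(y.n_elem) * std::log(2.0 * M_PI);
}

static arma::mat build_kernel(const arma::mat& D, double sigma, double alpha,
                              double beta, double sigma_n) {
  arma::mat K = sigma * arma::exp(-alpha * D);
  if (beta > 0.0) K %= arma::cos(beta * D);
  K.diag() += sigma_n + 1e-8;
  return K;
}

// [[Rcpp::export]]
double gp_nll_cpp(const arma::mat& D, const arma::vec& y, double sigma,
                  double alpha, double beta, double sigma_n) {
  if (!std::isfinite(sigma) || !std::isfinite(alpha) || sigma <= 0.0 ||
      alpha <= 0.0 || sigma_n < 0.0)
    return 1e10;
  return nll_from_chol(build_kernel(D, sigma, alpha, beta, sigma_n), y);
}

// Joint negative log-likelihood over several traces sharing one time grid and
// one set of hyperparameters (used for global noise calibration): a single
// factorisation serves every column of Y.
// [[Rcpp::export]]
double gp_nll_multi_cpp(const arma::mat& D, const arma::mat& Y, double sigma,
                        double alpha, double beta, double sigma_n) {
  if (!std::isfinite(sigma) || !std::isfinite(alpha) || sigma <= 0.0 ||
      alpha <= 0.0 || sigma_n < 0.0)
    return 1e10;
  arma::mat K = build_kernel(D, sigma, alpha, beta, sigma_n);
  arma::mat L;
  if (!arma::chol(L, K, "lower")) return 1e10;
  arma::mat V = arma::solve(arma::trimatl(L), Y);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  double n = static_cast<double>(Y.n_rows);
  double m = static_cast<double>(Y.n_cols);
  return 0.5 * m * logdet + 0.5 * arma::accu(V % V) +
         0.5 * n * m * std::log(2.0 * M_PI);
}
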