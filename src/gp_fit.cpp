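// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Multi-start Nelder-Mead maximum-likelihood fitting of OU / OUosc kernels,
// run entirely in compiled code: the optimiser is the hot path of the
// oscillation test (each synthetic-null trace is refitted with both models).
// Parameters are optimised on the log scale; an optional smooth-box log-prior
// on the decay rate (eta > 0 enables it) regularises short traces.

struct GPObjective {
  const arma::mat& D;
  const arma::vec& y;
  double sigma_n;
  bool osc;
  double prior_l, prior_u, prior_eta;

  double operator()(const arma::vec& par) const {
    double sigma = std::exp(par[0]);
    double alpha = std::exp(par[1]);
    double beta = osc ? std::exp(par[2]) : 0.0;
    if (!std::isfinite(sigma) || !std::isfinite(alpha) || sigma <= 0.0 ||
        alpha <= 0.0)
      return 1e10;
    arma::mat K = sigma * arma::exp(-alpha * D);
    if (beta > 0.0) K %= arma::cos(beta * D);
    K.diag() += sigma_n + 1e-8;
    arma::mat L;
    if (!arma::chol(L, K, "lower")) return 1e10;
    arma::vec v = arma::solve(arma::trimatl(L), y);
    double nll = arma::accu(arma::log(L.diag())) + 0.5 * arma::dot(v, v) +
                 0.5 * static_cast<double>(y.n_elem) * std::log(2.0 * M_PI);
    if (prior_eta > 0.0) {
      double s1 = 1.0 / (1.0 + std::exp(-prior_eta * (alpha - prior_l)));
      double s2 = 1.0 / (1.0 + std::exp(-prior_eta * (alpha - prior_u)));
      double pr = s1 * (1.0 - s2);
      nll -= std::log(std::max(pr, 1e-300));
    }
    return nll;
  }
};

// standard Nelder-Mead on an n-dimensional simplex
static double nelder_mead(const GPObjective& f, arma::vec& x, int maxit,
                          double tol) {
  const int n = x.n_elem;
  arma::mat simplex(n, n + 1);
  arma::vec fv(n + 1);
  simplex.col(0) = x;
  fv[0] = f(x);
  for (int i = 0; i < n; ++i) {
    arma::vec xi = x;
    xi[i] += 0.5;
    simplex.col(i + 1) = xi;
    fv[i + 1] = f(xi);
  }
  for (int iter = 0; iter < maxit; ++iter) {
    arma::uvec ord = arma::sort_index(fv);
    simplex = simplex.cols(ord);
    fv = fv(ord);
    if (fv[n] - fv[0] < tol * (std::abs(fv[0]) + 1.0)) break;
    arma::vec centroid = arma::mean(simplex.cols(0, n - 1), 1);
    arma::vec worst = simplex.col(n);
    arma::vec xr = centroid + (centroid - worst);          // reflect
    double fr = f(xr);
    if (fr < fv[0]) {
      arma::vec xe = centroid + 2.0 * (centroid - worst);  // expand
      double fe = f(xe);
      if (fe < fr) { simplex.col(n) = xe; fv[n] = fe; }
      else         { simplex.col(n) = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      simplex.col(n) = xr; fv[n] = fr;
    } else {
      arma::vec xc = centroid + 0.5 * (worst - centroid);  // contract
      double fc = f(xc);
      if (fc < fv[n]) { simplex.col(n) = xc; fv[n] = fc; }
      else {                                               // shrink
        for (int i = 1; i <= n; ++i) {
          simplex.col(i) = simplex.col(0) +
            0.5 * (simplex.col(i) - simplex.col(0));
          fv[i] = f(simplex.col(i));
        }
      }
    }
  }
  arma::uword best = fv.index_min();
  x = simplex.col(best);
  return fv[best];
}

// [[Rcpp::export]]
Rcpp::List gp_fit_cpp(const arma::mat& D, const arma::vec& y, bool osc,
                      double sigma_n, const arma::mat& starts,
                      double prior_l, double prior_u, double prior_eta,
                      int maxit = 300, double tol = 1e-6) {
  GPObjective f{D, y, sigma_n, osc, prior_l, prior_u, prior_eta};
  arma::vec best_par;
  double best_val = R_PosInf;
  for (arma::uword s = 0; s < starts.n_cols; ++s) {
    arma::vec x = starts.col(s);
    double val = nelder_mead(f, x, maxit, tol);
    if (val < best_val) { best_val = val; best_par = x; }
  }
  return Rcpp::List::create(Rcpp::_["par"] = best_par,
                            Rcpp::_["value"] = best_val);
}
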