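#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the delayed chemical Langevin equations for
// transcriptional autorepression:
//   dM/dt = -mu_m M + alpha_m G(P(t - tau)) + sqrt(mu_m M + alpha_m G) xi_m
//   dP/dt = -mu_p P + alpha_p M           + sqrt(mu_p P + alpha_p M) xi_p
// with G(P) = 1 / (1 + (P/P0)^n).  Transcription is inhibited for t < tau so
// that no transcription events are initiated at negative times; the delayed
// protein value is then always read from simulated history.  Molecule numbers
// are clipped at zero after each step (clip events are counted per trace).
// Gaussian increments come from R's RNG so runs are reproducible via set.seed.
// [[Rcpp::export]]
List cle_simulate_cpp(double alpha_m, double alpha_p, double mu_m, double mu_p,
                      double P0, double hill_n, int tau_steps,
                      double dt, int n_steps, int n_traces,
                      double M_init, double P_init, bool stochastic) {
  NumericMatrix M(n_steps + 1, n_traces);
  NumericMatrix P(n_steps + 1, n_traces);
  IntegerVector clipped(n_traces);
  const double sqdt = std::sqrt(dt);
  std::vector<double> m(n_steps + 1), p(n_steps + 1);
  for (int j = 0; j < n_traces; ++j) {
    m[0] = M_init;
    p[0] = P_init;
    int nclip = 0;
    for (int i = 0; i < n_steps; ++i) {
      double trans = 0.0;
      if (i >= tau_steps) {
        double pd = p[i - tau_steps];
        trans = alpha_m / (1.0 + std::pow(pd / P0, hill_n));
      }
      double prod_p = alpha_p * m[i];
      double mn = m[i] + dt * (trans - mu_m * m[i]);
      double pn = p[i] + dt * (prod_p - mu_p * p[i]);
      if (stochastic) {
        double am = mu_m * m[i] + trans;
        double ap = mu_p * p[i] + prod_p;
        if (am > 0.0) mn += std::sqrt(am) * sqdt * R::norm_rand();
        if (ap > 0.0) pn += std::sqrt(ap) * sqdt * R::norm_rand();
      }
      if (mn < 0.0) { mn = 0.0; ++nclip; }
      if (pn < 0.0) { pn = 0.0; ++nclip; }
      m[i + 1] = mn;
      p[i + 1] = pn;
    }
    clipped[j] = nclip;
    for (int i = 0; i <= n_steps; ++i) {
      M(i, j) = m[i];
      P(i, j) = p[i];
    }
  }
  return List::create(_["mrna"] = M, _["protein"] = P, _["n_clipped"] = clipped);
}
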