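test_that("Hill repression has its defining values and monotonicity", {
  expect_equal(hill_repression(1000, 1000, 3), 0.5)
  expect_equal(hill_repression(0, 1000, 3), 1)
  expect_equal(hill_repression(2000, 1000, 4), 1 / 17)
  p <- seq(0, 5000, by = 100)
  expect_true(all(diff(hill_repression(p, 1000, 4)) < 0))
  expect_error(hill_repression(-1, 1000, 3), "negative")
})

test_that("noise-free Langevin trajectories equal the deterministic limit", {
  p <- aperiodic_point()
  cfg <- simulation_config(t_eq = 0, t_obs = 600, n_traces = 2)
  a <- simulate_cle(p, cfg, stochastic = FALSE)
  b <- simulate_deterministic(p, cfg)
  expect_lt(max(abs(a$protein[, 1] - b$protein)), 1e-6)
  expect_lt(max(abs(a$protein[, 1] - a$protein[, 2])), 1e-12)
})

test_that("decay-only system relaxes to zero and counts stay non-negative", {
  p <- model_parameters(alpha_m = 1e-6, alpha_p = 1, P0 = 100, hill_n = 2,
                        tau = 10)
  cfg <- simulation_config(t_eq = 0, t_obs = 2000, n_traces = 1,
                           M_init = 50, P_init = 500)
  d <- simulate_deterministic(p, cfg)
  expect_lt(tail(d$protein, 1), 1)
  set.seed(1)
  s <- simulate_cle(oscillatory_point(), simulation_config(n_traces = 3))
  expect_true(all(s$protein >= 0) && all(s$mrna >= 0))
})

test_that("steady state solves both balance equations uniquely", {
  p <- oscillatory_point()
  ss <- steady_state(p)
  # plug back: residuals of both balances
  expect_lt(abs(p$mu_m * ss$mrna -
                  p$alpha_m * hill_repression(ss$protein, p$P0, p$hill_n)) /
              (p$mu_m * ss$mrna), 1e-9)
  expect_lt(abs(p$mu_p * ss$protein - p$alpha_p * ss$mrna) /
              (p$mu_p * ss$protein), 1e-9)
  # no repression limit: linear fixed point
  pfree <- model_parameters(alpha_m = 2, alpha_p = 3, P0 = 1e12, hill_n = 4,
                            tau = 10)
  expect_equal(steady_state(pfree)$protein,
               2 * 3 / (pfree$mu_m * pfree$mu_p), tolerance = 1e-6)
  # comparative statics: raising the repression threshold raises P*
  P0s <- c(1e4, 3e4, 6e4, 1e5)
  stars <- vapply(P0s, function(P0) {
    pp <- p; pp$P0 <- P0; steady_state(pp)$protein
  }, numeric(1))
  expect_true(all(diff(stars) > 0))
})

test_that("deterministic dynamics: limit cycle when unstable, convergence when stable", {
  posc <- oscillatory_point()
  expect_true(is_oscillatory_deterministic(posc))
  d <- simulate_deterministic(posc, simulation_config(t_eq = 3000,
                                                      t_obs = 3000,
                                                      n_traces = 1))
  peaks <- which(diff(sign(diff(d$protein))) == -2) + 1
  amps <- d$protein[peaks]
  expect_gt(length(amps), 3)
  # sustained amplitude: last three peak heights agree within 2%
  last3 <- tail(amps, 3)
  expect_lt(diff(range(last3)) / mean(last3), 0.02)

  pstab <- aperiodic_point()
  expect_false(is_oscillatory_deterministic(pstab))
  d2 <- simulate_deterministic(pstab, simulation_config(t_obs = 4000,
                                                        n_traces = 1))
  expect_equal(tail(d2$protein, 1), steady_state(pstab)$protein,
               tolerance = 1e-4)
})

test_that("deterministic solver agrees with an independent DDE integrator", {
  skip_if_not_installed("deSolve")
  p <- model_parameters(alpha_m = 1, alpha_p = 2, P0 = 1000, hill_n = 4,
                        tau = 30)
  cfg <- simulation_config(t_eq = 0, t_obs = 500, n_traces = 1, dt = 0.1)
  mine <- simulate_deterministic(p, cfg)
  fn <- function(t, y, parms) {
    trans <- if (t < p$tau) 0 else
      p$alpha_m * hill_repression(deSolve::lagvalue(t - p$tau, 2),
                                  p$P0, p$hill_n)
    list(c(trans - p$mu_m * y[1], p$alpha_p * y[1] - p$mu_p * y[2]))
  }
  ref <- deSolve::dede(c(10, 1000), times = seq(0, 500, by = 0.1), func = fn,
                       parms = NULL)
  expect_lt(max(abs(mine$protein - ref[, 3]) / pmax(ref[, 3], 1)), 0.01)
})

test_that("no-delay negative feedback cannot oscillate; Hopf test needs delay", {
  p0 <- oscillatory_point()
  expect_true(is_oscillatory_deterministic(p0))
  # removing the delay stabilises the same feedback loop
  p0$tau <- 0
  expect_false(is_oscillatory_deterministic(p0))
})

test_that("LNA spectrum: no-feedback limit matches the linear cascade form", {
  p <- model_parameters(alpha_m = 2, alpha_p = 3, P0 = 1e12, hill_n = 4,
                        tau = 25)
  f <- seq(0, 0.02, by = 1e-4)
  ps <- lna_power_spectrum(p, f)
  Ms <- 2 / p$mu_m; Ps <- 2 * 3 / (p$mu_m * p$mu_p)
  w <- 2 * pi * f
  cascade <- 2 * (3^2 * 2 * p$mu_m * Ms + (w^2 + p$mu_m^2) * 2 * p$mu_p * Ps) /
    ((w^2 + p$mu_m^2) * (w^2 + p$mu_p^2))
  expect_equal(ps$power, cascade, tolerance = 1e-6)
  expect_true(all(ps$power >= 0))
  expect_error(lna_power_spectrum(p, c(0.01, 0.001)), "sorted")
})

test_that("LNA variance and spectral peak agree with ensemble simulation", {
  p <- aperiodic_point()
  set.seed(10)
  sim <- simulate_cle(p, simulation_config(n_traces = 200))
  es <- expression_stats(sim$protein)
  expect_equal(sqrt(lna_variance(p)), es$sd_protein, tolerance = 0.1)
  pe <- model_parameters(alpha_m = 39.93, alpha_p = 21.56, P0 = 24201.01,
                         hill_n = 4.78, tau = 33)
  set.seed(11)
  sime <- simulate_cle(pe, simulation_config(n_traces = 200))
  ps <- ensemble_power_spectrum(sime$protein, dt = 1)
  keep <- ps$frequencies > 0
  sim_peak <- ps$frequencies[keep][which.max(ps$power[keep])]
  lna <- lna_power_spectrum(pe, ps$frequencies[keep])
  lna_peak <- lna$frequencies[which.max(lna$power)]
  df <- ps$frequencies[2] - ps$frequencies[1]
  expect_lt(abs(sim_peak - lna_peak), 1.5 * df)
  # peak height within the sampling-error bound
  expect_lt(abs(max(lna$power) - max(ps$power[keep])) / max(lna$power), 0.2)
})
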