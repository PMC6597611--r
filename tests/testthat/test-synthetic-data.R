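test_that("GP samples match their covariance: marginal variance and kernel", {
  set.seed(1)
  # marginal variance at a single timepoint
  draws <- replicate(4000, gen_gp_trace("OU", 1, 0.01, times = 0))
  expect_equal(var(draws), 1, tolerance = 0.1)
  # empirical covariance over many draws matches the analytic kernel
  times <- c(0, 15, 30, 60, 120)
  Y <- replicate(3000, gen_gp_trace("OUosc", 2, 0.005, 2 * pi / 200, times))
  emp <- tcrossprod(Y - rowMeans(Y)) / (ncol(Y) - 1)
  D <- abs(outer(times, times, "-"))
  expect_lt(max(abs(emp - 2 * exp(-0.005 * D) * cos(2 * pi / 200 * D))), 0.25)
})

test_that("OUosc frequency sets the autocorrelation zero crossing", {
  # quarter period: kernel cos(beta tau) first vanishes at tau = 50 min
  set.seed(2)
  tt <- seq(0, 9999)
  y <- gen_gp_trace("OUosc", 1, 0.004, 2 * pi / 200, tt)
  ac <- stats::acf(y, lag.max = 120, plot = FALSE)$acf[, 1, 1]
  first_zero <- which(ac < 0)[1] - 1
  expect_gt(first_zero, 40)
  expect_lt(first_zero, 60)
})

test_that("zero OUosc frequency degenerates to the OU kernel", {
  D <- abs(outer(std_times(10), std_times(10), "-"))
  expect_identical(ultradyn:::ou_kernel(D, 1.5, 0.01, 0),
                   1.5 * exp(-0.01 * D))
})

test_that("technical noise is additive white noise of the stated SD", {
  expect_identical(add_technical_noise(1:10, 0), 1:10)
  set.seed(3)
  out <- add_technical_noise(rep(5, 20000), 0.7)
  expect_equal(sd(out), 0.7, tolerance = 0.05)
  expect_error(add_technical_noise(1:5, -1), "non-negative")
  # SNR: noise at 10% of signal SD gives variance ratio ~100
  set.seed(4)
  tt <- seq(0, 9999)
  sig <- gen_gp_trace("OU", 4, 0.01, times = tt)
  noise <- add_technical_noise(sig, 0.1 * sd(sig)) - sig
  expect_equal(var(sig) / var(noise), 100, tolerance = 0.2)
})

test_that("trend generator honours level, drop and shoulder", {
  tt <- std_times(60)
  expect_equal(gen_trend("stable", tt, list(level = 100)), rep(100, 60))
  dec <- gen_trend("declining", tt,
                   list(level = 100, onset = 240, duration = 300,
                        drop_frac = 0.6))
  expect_equal(tail(dec, 1), 40, tolerance = 1)
  # change-point oracle: steepest-tangent/plateau intersection on the
  # noiseless trend recovers the configured 4-h shoulder within one sample
  fine <- seq(0, 885, by = 1)
  trend <- gen_trend("declining", fine,
                     list(level = 100, onset = 240, duration = 300,
                          drop_frac = 0.6))
  slope <- diff(trend)
  imax <- which.min(slope)
  cp <- fine[imax] - (trend[1] - trend[imax]) / abs(slope[imax])
  expect_lt(abs(cp - 240), 15)
  expect_error(gen_trend("bogus", tt, list(level = 1)))
})

test_that("population generator composes trend + signal + noise with labels", {
  cfg <- trace_gen_config(n_cells = 12, seed = 7,
                          archetype_mix = c(1, 0, 0, 0))
  pop <- gen_population(cfg)
  expect_setequal(unique(pop$label), 1L)
  # stable archetype: stored trend is constant per cell
  expect_true(all(tapply(pop$trend, pop$cell_id, sd) == 0))
  # bit-reproducible under the seed
  pop2 <- gen_population(cfg)
  expect_identical(pop$value, pop2$value)
  # residual after removing the stored trend is the stationary part
  resid <- pop$value - pop$trend
  expect_lt(abs(mean(resid)), 2 * sd(resid))
  expect_error(gen_population(trace_gen_config(archetype_mix = c(0, 0, 0, 0))),
               "sum to 1")
})

test_that("snapshot generator yields paired tables calibratable to the scale", {
  snap <- gen_snapshot(snapshot_gen_config(n_cells = 400, true_scale = 3,
                                           seed = 11))
  expect_identical(snap$intensity$cell_id, snap$concentration$cell_id)
  cal <- qq_calibrate(snap$intensity$intensity,
                      snap$concentration$concentration_nM)
  expect_equal(cal$scale, 3, tolerance = 1e-6)
  expect_gt(cal$r_squared, 0.99)
  # n = 2: neighbour differences defined and symmetric
  two <- data.frame(x_um = c(0, 10), y_um = c(0, 0),
                    concentration_nM = c(100, 150))
  ns <- neighbour_stats(two, split_at = NULL)
  expect_equal(ns$per_cell$neighbour_diff, c(50, 50))
})

test_that("FCS curve generator has the standard limits", {
  lags <- exp(seq(log(1e-6), log(1), length.out = 80))
  one <- gen_fcs_curve(lags, N_molecules = 50, frac_fast = 1,
                       triplet_frac = 0, tau_fast = 1e-4)
  S <- 5
  expect_equal(one$G,
               (1 / 50) / ((1 + lags / 1e-4) * sqrt(1 + lags / (S^2 * 1e-4))),
               tolerance = 1e-12)
  # amplitude scales as 1/N
  twoN <- gen_fcs_curve(lags, N_molecules = 100, frac_fast = 1,
                        triplet_frac = 0, tau_fast = 1e-4)
  expect_equal(one$G[1] / twoN$G[1], 2, tolerance = 1e-12)
  expect_error(gen_fcs_curve(lags, 50, frac_fast = 1.5), "fraction")
})

test_that("trace CSV round-trips with its sidecar config", {
  pop <- gen_population(trace_gen_config(n_cells = 3, seed = 5))
  path <- file.path(tempdir(), "traces.csv")
  write_traces_csv(pop, path)
  back <- read_traces_csv(path)
  expect_equal(back$value, pop$value)
  expect_equal(attr(back, "config")$seed, 5L)
})
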