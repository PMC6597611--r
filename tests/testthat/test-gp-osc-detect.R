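test_that("detrending separates slow trends from ultradian oscillation", {
  tt <- std_times(49)
  # constant trace
  d0 <- detrend(rep(7, 49), tt)
  expect_equal(d0$trend, rep(7, 49))
  expect_equal(d0$detrended, rep(0, 49))
  # linear decline + 3-h sinusoid
  osc <- 10 * sin(2 * pi * tt / 180)
  decline <- 100 - 0.08 * tt
  d <- detrend(decline + osc, tt)
  interior <- 8:42
  retained <- diff(range(d$detrended[interior])) / diff(range(osc[interior]))
  expect_gt(retained, 0.8)
  trend_drop <- d$trend[1] - tail(d$trend, 1)
  expect_gt(trend_drop / (decline[1] - tail(decline, 1)), 0.95)
  expect_equal(mean(d$detrended), 0, tolerance = 1e-10)
  # monotone decline alone: residual SD is far below the decline magnitude
  d2 <- detrend(decline, tt)
  expect_lt(sd(d2$detrended), 0.05 * diff(range(decline)))
  expect_error(detrend(1:5, 1:5), "few")
})

test_that("covariance fits recover planted hyperparameters", {
  set.seed(30)
  tt <- std_times(45)
  # OU decay rate within a factor of two (median over traces)
  alphas <- vapply(1:30, function(i) {
    y <- add_technical_noise(gen_gp_trace("OU", 1, 1 / 100, times = tt), 0.1)
    fit_covariance(y, tt, "OU", sigma_n = 0.01)$alpha
  }, numeric(1))
  expect_gt(median(alphas), 0.005)
  expect_lt(median(alphas), 0.02)
  # OUosc period within 20% for good-quality oscillations
  pers <- vapply(1:30, function(i) {
    y <- add_technical_noise(
      gen_gp_trace("OUosc", 1, 1 / 500, 2 * pi / 180, tt), 0.1)
    fit_covariance(y, tt, "OUosc", sigma_n = 0.01)$period_h
  }, numeric(1))
  expect_lt(abs(median(pers) - 3) / 3, 0.2)
})

test_that("model nesting: OUosc contains OU and the LLR reflects it", {
  set.seed(31)
  tt <- std_times(45)
  D <- abs(outer(tt, tt, "-"))
  y <- add_technical_noise(gen_gp_trace("OU", 1, 1 / 100, times = tt), 0.1)
  fou <- fit_covariance(y, tt, "OU", sigma_n = 0.01)
  fosc <- fit_covariance(y, tt, "OUosc", sigma_n = 0.01)
  # beta -> 0 reproduces the OU likelihood at the same (sigma, alpha)
  ll_beta0 <- -ultradyn:::gp_nll_cpp(D, y, fou$sigma, fou$alpha, 0, 0.01)
  ll_tiny <- -ultradyn:::gp_nll_cpp(D, y, fou$sigma, fou$alpha, 1e-9, 0.01)
  expect_equal(ll_beta0, ll_tiny, tolerance = 1e-8)
  expect_gte(llr_score(fou, fosc), -1e-4)
  expect_error(llr_score(fou, fit_covariance(y[1:40], tt[1:40], "OUosc",
                                             sigma_n = 0.01)),
               "same trace")
  # a strongly periodic trace scores above the OU-null 95th percentile
  set.seed(32)
  yper <- add_technical_noise(
    gen_gp_trace("OUosc", 1, 1 / 600, 2 * pi / 180, tt), 0.1)
  per_llr <- llr_score(fit_covariance(yper, tt, "OU", sigma_n = 0.01),
                       fit_covariance(yper, tt, "OUosc", sigma_n = 0.01))
  null_llr <- vapply(1:40, function(i) {
    yn <- add_technical_noise(gen_gp_trace("OU", 1, 1 / 100, times = tt), 0.1)
    llr_score(fit_covariance(yn, tt, "OU", sigma_n = 0.01),
              fit_covariance(yn, tt, "OUosc", sigma_n = 0.01))
  }, numeric(1))
  expect_gt(per_llr, quantile(null_llr, 0.95))
})

test_that("length normalisation makes the LLR comparable across trace lengths", {
  set.seed(33)
  tt <- std_times(44)
  y <- add_technical_noise(
    gen_gp_trace("OUosc", 1, 1 / 500, 2 * pi / 180, tt), 0.1)
  tt2 <- c(tt, tt + 660)
  y2 <- c(y, y)
  llr1 <- llr_score(fit_covariance(y, tt, "OU", sigma_n = 0.01),
                    fit_covariance(y, tt, "OUosc", sigma_n = 0.01))
  llr2 <- llr_score(fit_covariance(y2, tt2, "OU", sigma_n = 0.01),
                    fit_covariance(y2, tt2, "OUosc", sigma_n = 0.01))
  expect_lt(abs(llr2 - llr1), 0.6 * max(llr1, 0.05))
})

test_that("global noise calibration recovers a planted noise fraction", {
  set.seed(34)
  tt <- std_times(45)
  Y <- noisy_gp_traces(120, tt, kind = "OUosc", lengthscale = 1 / 300,
                       period_min = 180, noise_frac = 0.1)
  det <- apply(Y, 2, function(y) detrend(y, tt)$detrended)
  cal <- calibrate_noise(det, tt)
  expect_gte(cal$noise_fraction, 0.05)
  expect_lte(cal$noise_fraction, 0.15)
  expect_s3_class(cal$profile, "data.frame")
  # noise-free data: profile maximised at the smallest candidates
  set.seed(35)
  Y0 <- noisy_gp_traces(60, tt, kind = "OUosc", lengthscale = 1 / 300,
                        noise_frac = 0)
  det0 <- apply(Y0, 2, function(y) detrend(y, tt)$detrended)
  expect_warning(cal0 <- calibrate_noise(det0, tt), "boundary")
  expect_lte(cal0$noise_fraction, 0.06)
})

test_that("FDR classification is conservative on nulls and sensitive to oscillators", {
  tt <- std_times(45)
  set.seed(36)
  Y <- cbind(noisy_gp_traces(30, tt, kind = "OU", lengthscale = 1 / 100),
             noisy_gp_traces(30, tt, kind = "OUosc", lengthscale = 1 / 300,
                             period_min = 180))
  calls <- classify_oscillators(Y, tt, n_null_per_cell = 10L)
  expect_identical(nrow(calls), 60L)
  # one shared calibrated noise variance across all cells
  expect_identical(length(unique(calls$sigma_n)), 1L)
  expect_true(all(calls$q_value >= 0 & calls$q_value <= 1))
  # sensitivity above one half on the planted oscillators at FDR 3%
  expect_gt(mean(calls$oscillatory[31:60]), 0.5)
  # false positives among the OU half stay rare
  expect_lte(mean(calls$oscillatory[1:30]), 0.1)
  # periods of detected oscillators centre on the planted 3 h
  det_per <- calls$period_h[31:60][calls$oscillatory[31:60]]
  expect_lt(abs(median(det_per) - 3), 0.6)
  # empty input passes through
  empty <- classify_oscillators(matrix(numeric(0), nrow = 0), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("fitted periods on an oscillatory population match the planted distribution", {
  set.seed(37)
  tt <- std_times(45)
  planted <- exp(rnorm(60, log(180), 0.15))
  fitted <- vapply(planted, function(per) {
    y <- add_technical_noise(
      gen_gp_trace("OUosc", 1, 1 / 500, 2 * pi / per, tt), 0.1)
    fit_covariance(y, tt, "OUosc", sigma_n = 0.01)$period_h * 60
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(fitted, planted))
  expect_gt(ks$p.value, 0.01)
})
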