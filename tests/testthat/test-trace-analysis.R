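test_that("Hilbert reconstruction tracks amplitude and phase", {
  tt <- seq(0, 1200)
  y <- 4 * sin(2 * pi * tt / 200)
  hil <- hilbert_reconstruct(y, rep(100, length(tt)), tt)
  interior <- 150:1050
  expect_equal(mean(hil$amplitude[interior]), 4, tolerance = 0.05)
  expect_equal(hil$signal, y + 100)
  # phase advances by 2 pi per period
  up <- ultradyn:::unwrap_phase(hil$phase)
  expect_equal((up[1001] - up[201]) / (2 * pi), 800 / 200, tolerance = 0.05)
  expect_error(hilbert_reconstruct(rep(0, 10), rep(1, 10), 1:10), "constant")
  # decaying envelope is tracked away from edges
  env <- seq(5, 1, length.out = length(tt))
  hil2 <- hilbert_reconstruct(env * sin(2 * pi * tt / 200), rep(0, length(tt)), tt)
  core <- 220:980
  expect_lt(max(abs(hil2$amplitude[core] - env[core]) / env[core]), 0.1)
})

test_that("phase unwraps monotonically for strictly periodic input", {
  tt <- seq(0, 1000)
  hil <- hilbert_reconstruct(sin(2 * pi * tt / 250), rep(0, length(tt)), tt)
  up <- ultradyn:::unwrap_phase(hil$phase)
  expect_true(all(diff(up[50:950]) > 0))
})

test_that("fold changes respond to the trend exactly as constructed", {
  tt <- seq(0, 1320, by = 15)
  osc <- 25 * sin(2 * pi * tt / 180)     # oscillates 100 <-> 50 on flat 75
  flat <- hilbert_reconstruct(osc, rep(75, length(tt)), tt)
  fc_flat <- peak_trough_fold_changes(flat)
  expect_true(all(abs(fc_flat$pairs$fold_change - 2) < 0.15))
  expect_equal(fc_flat$max_fold_change, 2, tolerance = 0.15)
  # scale invariance
  scaled <- hilbert_reconstruct(3 * osc, rep(3 * 75, length(tt)), tt)
  expect_equal(peak_trough_fold_changes(scaled)$max_fold_change,
               fc_flat$max_fold_change, tolerance = 1e-9)
  # a two-fold declining trend amplifies the instantaneous drop
  trend <- seq(100, 50, length.out = length(tt))
  dec <- hilbert_reconstruct(osc, trend, tt)
  fc_dec <- peak_trough_fold_changes(dec)
  expect_gt(fc_dec$max_fold_change, fc_flat$max_fold_change)
  # with the trend removed the enrichment disappears
  expect_lt(fc_flat$max_fold_change / fc_dec$max_fold_change, 1)
  # no crossings: empty report
  none <- hilbert_reconstruct(exp(seq(0, 1, length.out = 30)) -
                                mean(exp(seq(0, 1, length.out = 30))),
                              rep(0, 30), seq(0, 29))
  expect_s3_class(peak_trough_fold_changes(none), "fold_change_report")
})

test_that("standardisation follows the population-SD convention", {
  expect_equal(standardize(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(standardize(standardize(x)), standardize(x), tolerance = 1e-12)
  expect_equal(standardize(2.5 * x + 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(1, 10)), "constant")
})

test_that("hierarchical clustering separates planted archetypes", {
  set.seed(40)
  tt <- std_times(45)
  flat <- replicate(15, standardize(rnorm(45, 100, 3)))
  declining <- replicate(15, standardize(100 - 1.5 * seq_len(45) + rnorm(45, 0, 3)))
  mat <- t(cbind(flat, declining))
  cl <- hcluster(mat, k = 2)
  expect_identical(length(unique(cl$labels[1:15])), 1L)
  expect_identical(length(unique(cl$labels[16:30])), 1L)
  expect_false(cl$labels[1] == cl$labels[16])
  expect_true(all(c("k", "wss", "silhouette") %in% names(cl$diagnostics)))
  expect_true(all(diff(cl$diagnostics$wss) < 1e-9))
})

test_that("COV over expanding windows grows with a decline, not with stationarity", {
  tt <- seq(0, 17.25 * 60, by = 15)
  const <- cov_over_windows(rep(10, length(tt)), tt)
  expect_true(all(const$cov_percent == 0))
  dec <- cov_over_windows(100 - 0.06 * tt, tt)
  expect_true(all(diff(dec$cov_percent) > 0))
  set.seed(41)
  stat <- cov_over_windows(100 + gen_gp_trace("OU", 9, 0.05, times = tt), tt)
  expect_lt(diff(range(stat$cov_percent)) / mean(stat$cov_percent), 0.8)
  expect_message(cov_over_windows(rep(1, 10), seq(0, 135, by = 15)),
                 "omitted")
})

test_that("shoulder point marks the onset of a >50% decline", {
  tt <- seq(0, 900, by = 15)
  expect_null(shoulder_point(rep(100, length(tt)), tt))
  piece <- ifelse(tt <= 450, 100, pmax(100 - 0.4 * (tt - 450), 40))
  sp <- shoulder_point(piece, tt, trend = piece)
  expect_lt(abs(sp - 450), 16)
  shallow <- ifelse(tt <= 450, 100, pmax(100 - 0.2 * (tt - 450), 70))
  expect_null(shoulder_point(shallow, tt, trend = shallow))
})

test_that("z-depth correction removes the planted depth gradient", {
  set.seed(42)
  tt <- std_times(20)
  cells <- do.call(rbind, lapply(1:30, function(i) {
    z <- runif(1, 0, 30)
    data.frame(cell_id = i, time_min = tt,
               value = 100 - 2 * z + rnorm(20, 0, 1), z_um = z)
  }))
  corr <- zdepth_correct(cells)
  fit <- attr(corr, "zfit")
  expect_equal(unname(fit["slope"]), -2, tolerance = 0.1)
  # planted slope -2 at z = 10 gives a +20 offset on the whole trace
  one <- cells[cells$cell_id == 1, ]
  expect_equal(corr$value[cells$cell_id == 1] - one$value,
               rep(-fit[["slope"]] * one$z_um[1], 20))
  # after correction the initial intensities no longer depend on z
  first <- corr[!duplicated(corr$cell_id), ]
  refit <- lm(value ~ z_um, data = first)
  expect_lt(abs(coef(refit)[2]), 0.3)
  # slope-zero input passes through
  flat <- cells; flat$value <- 100 + rnorm(nrow(flat), 0, 1e-6)
  out <- zdepth_correct(flat)
  expect_equal(out$value, flat$value, tolerance = 1e-3)
})

test_that("amplitude death is detected after, not before, a planted onset", {
  set.seed(43)
  tt <- seq(0, 16 * 60, by = 15)
  mk <- function(decay) do.call(rbind, lapply(1:12, function(i) {
    amp <- if (decay) ifelse(tt < 600, 10, 10 * exp(-(tt - 600) / 150))
    else rep(10, length(tt))
    data.frame(cell_id = i, time_min = tt,
               amplitude = pmax(amp + rnorm(length(tt), 0, 0.6), 0),
               group = if (decay) "decaying" else "constant")
  }))
  res <- amplitude_death(rbind(mk(TRUE), mk(FALSE)), bin_h = 2)
  dec <- res[res$group == "decaying", ]
  con <- res[res$group == "constant", ]
  expect_true(all(con$p_value > 0.01, na.rm = TRUE))
  expect_true(any(dec$p_value[dec$epoch_start_h >= 12] < 0.01, na.rm = TRUE))
  expect_true(all(dec$p_value[dec$epoch_start_h < 10] > 0.01, na.rm = TRUE))
  # degenerate all-zero group flagged; tiny group excluded with message
  zero <- data.frame(cell_id = rep(1:3, each = 4),
                     time_min = rep(c(0, 60, 120, 180), 3),
                     amplitude = 0, group = "zero")
  expect_true(all(amplitude_death(zero)$degenerate))
  expect_message(amplitude_death(zero[zero$cell_id < 3, ]), "fewer than 3")
})

test_that("positional summaries are exact on a toy track", {
  ts <- track_summary(c(0, 3, 3), c(0, 4, 8))
  expect_equal(ts$total_distance, 9)
  expect_equal(ts$displacement, sqrt(9 + 64))
  expect_equal(ts$mean_step, 4.5)
})
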