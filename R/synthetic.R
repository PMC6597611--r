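## Synthetic-data generators -------------------------------------------------
##
## Every downstream stage of the package (clustering, oscillation detection,
## Hilbert analytics, calibration) is exercised on data produced here, with
## the statistical structure those analyses assume: stationary OU / damped-
## cosine Gaussian-process fluctuations superimposed on slow trends, additive
## white technical noise, and paired snapshot intensity/concentration tables.

#' Configuration for the single-cell trace generator
#'
#' Defaults emulate live-imaging experiments in embryonic tissue: traces of
#' roughly 11 h sampled every 15 min (45 timepoints), technical noise with a
#' standard deviation of 10% of the signal SD, and a population mixing four
#' dynamic archetypes (stable high, stable lower with a gentle drift, early
#' decline, delayed decline) in proportions echoing observed cluster sizes.
#'
#' @param duration trace length in minutes.
#' @param sampling_interval sampling interval in minutes.
#' @param n_cells number of cells.
#' @param noise_fraction technical-noise SD as a fraction of the SD of the
#'   stationary fluctuation signal.
#' @param trend_kind default trend for [gen_trend()] convenience calls,
#'   `"stable"` or `"declining"`.
#' @param archetype_mix proportions over the four archetypes; must sum to 1.
#' @param level_cv coefficient of variation of per-cell mean levels within an
#'   archetype (the marginal distribution of cell means is a modelling choice;
#'   lognormal with this CV).
#' @param seed integer seed used by [gen_population()].
#' @return a list of class `trace_gen_config`.
#' @export
trace_gen_config <- function(duration = 660, sampling_interval = 15,
                             n_cells = 200, noise_fraction = 0.1,
                             trend_kind = c("stable", "declining"),
                             archetype_mix = c(0.15, 0.18, 0.37, 0.30),
                             level_cv = 0.15, seed = 1L) {
  trend_kind <- match.arg(trend_kind)
  stopifnot(duration > 0, sampling_interval > 0, n_cells >= 1,
            noise_fraction >= 0, level_cv >= 0)
  if (length(archetype_mix) != 4L || any(archetype_mix < 0))
    stop("archetype_mix must be four non-negative proportions")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype proportions must sum to 1")
  structure(list(duration = duration, sampling_interval = sampling_interval,
                 n_cells = n_cells, noise_fraction = noise_fraction,
                 trend_kind = trend_kind, archetype_mix = archetype_mix,
                 level_cv = level_cv, seed = as.integer(seed)),
            class = "trace_gen_config")
}

#' Configuration for the snapshot generator
#'
#' @param n_cells number of segmented nuclei.
#' @param true_scale nM of protein per intensity unit (the quantity that
#'   quantile-quantile calibration should recover).
#' @param concentration_mean,concentration_sd mean and SD (nM) of the
#'   lognormal nuclear-concentration distribution.
#' @param spatial_extent side length (um) of the square tissue region over
#'   which centroids are placed uniformly.
#' @param intensity_noise_sd SD of additive measurement noise on intensities,
#'   in intensity units (0 = noiseless).
#' @param seed integer seed.
#' @export
snapshot_gen_config <- function(n_cells = 500, true_scale = 3,
                                concentration_mean = 140,
                                concentration_sd = 70,
                                spatial_extent = 100,
                                intensity_noise_sd = 0, seed = 1L) {
  stopifnot(n_cells >= 2, true_scale > 0, concentration_mean > 0,
            concentration_sd > 0, spatial_extent > 0, intensity_noise_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), true_scale = true_scale,
                 concentration_mean = concentration_mean,
                 concentration_sd = concentration_sd,
                 spatial_extent = spatial_extent,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "snapshot_gen_config")
}

ou_kernel <- function(D, variance, lengthscale, frequency = 0) {
  K <- variance * exp(-lengthscale * D)
  if (frequency > 0) K <- K * cos(frequency * D)
  K
}

#' Draw one sample path from an OU or damped-cosine Gaussian process
#'
#' `kind = "OU"` uses the covariance `sigma * exp(-alpha * |dt|)`; `"OUosc"`
#' multiplies it by `cos(beta * dt)`.  On long uniform grids the draw uses the
#' exact Markov recursion of the (complex) OU process; otherwise a Cholesky
#' factorisation with a fixed diagonal jitter of 1e-8 is used.  Both routes
#' are exact samplers of the stated covariance (up to the jitter).
#'
#' @param kind `"OU"` or `"OUosc"`.
#' @param variance marginal variance `sigma` of the process.
#' @param lengthscale decay rate `alpha` (1/min) of peak-to-peak correlations.
#' @param frequency angular frequency `beta` (rad/min); ignored for `"OU"`.
#' @param times sampling times in minutes, strictly increasing.
#' @return numeric vector of process values at `times`.
#' @export
gen_gp_trace <- function(kind = c("OU", "OUosc"), variance, lengthscale,
                         frequency = 0, times) {
  kind <- match.arg(kind)
  stopifnot(variance > 0, lengthscale > 0)
  if (kind == "OUosc" && !(frequency > 0))
    stop("OUosc requires a positive frequency")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  beta <- if (kind == "OUosc") frequency else 0
  n <- length(times)
  if (n == 1L) return(rnorm(1L, 0, sqrt(variance)))
  if (n > 400L && is_uniform_grid(times)) {
    ## exact recursion: the damped-cosine kernel is the real part of a
    ## circularly-symmetric complex OU process
    dt <- times[2L] - times[1L]
    rho <- exp(complex(real = -lengthscale * dt, imaginary = beta * dt))
    innov_sd <- sqrt(variance * (1 - exp(-2 * lengthscale * dt)))
    zr <- rnorm(n); zi <- rnorm(n)
    z <- complex(real = rnorm(1L, 0, sqrt(variance)),
                 imaginary = rnorm(1L, 0, sqrt(variance)))
    out <- numeric(n)
    out[1L] <- Re(z)
    for (i in 2L:n) {
      z <- rho * z + complex(real = innov_sd * zr[i], imaginary = innov_sd * zi[i])
      out[i] <- Re(z)
    }
    return(out)
  }
  D <- abs(outer(times, times, "-"))
  K <- ou_kernel(D, variance, lengthscale, beta)
  diag(K) <- diag(K) + 1e-8
  L <- tryCatch(chol(K), error = function(e)
    stop("covariance not positive definite after jitter: ", conditionMessage(e)))
  as.numeric(crossprod(L, rnorm(n)))
}

#' Add white technical noise to a trace
#'
#' Adds an independent zero-mean Gaussian perturbation of the stated SD to
#' every timepoint, the standard model for detector noise on fluorescence
#' intensities.
#'
#' @param trace numeric vector of intensities.
#' @param noise_sd noise standard deviation (>= 0).
#' @export
add_technical_noise <- function(trace, noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(trace)
  trace + rnorm(length(trace), 0, noise_sd)
}

#' Deterministic long-term trend
#'
#' `"stable"` returns a constant mean.  `"declining"` returns a logistic
#' decline parameterised by the shoulder `onset` (minutes), the decline
#' `duration` (minutes) and the `drop_frac` (total fractional drop, >= 0.5 for
#' the differentiation-like archetypes).  The shoulder is defined as the
#' intersection of the steepest-descent tangent with the initial plateau, the
#' usual operational definition of a sigmoid shoulder, so a change-point fit
#' on the noiseless trend recovers `onset`.
#'
#' @param kind `"stable"` or `"declining"`.
#' @param times sampling times (minutes), monotone increasing.
#' @param params list with `level` and, for `"declining"`, `onset`,
#'   `duration`, `drop_frac`.
#' @export
gen_trend <- function(kind = c("stable", "declining"), times, params) {
  if (is.unsorted(times)) stop("times must be monotone increasing")
  kind <- match.arg(kind)
  level <- params$level
  stopifnot(is.numeric(level), level > 0)
  if (kind == "stable") return(rep(level, length(times)))
  onset <- params$onset
  duration <- params$duration
  drop_frac <- params$drop_frac
  stopifnot(onset >= 0, duration > 0, drop_frac > 0, drop_frac < 1)
  s <- duration / 10        # logistic time constant: decline spans ~duration
  mid <- onset + 2 * s      # tangent-plateau intersection lands at `onset`
  level * (1 - drop_frac / (1 + exp(-(times - mid) / s)))
}

default_archetypes <- function() {
  path <- system.file("extdata", "archetypes.yaml", package = "ultradyn")
  yaml::read_yaml(path)
}

#' Generate a labelled population of synthetic single-cell traces
#'
#' Each trace is composed additively as trend + Gaussian-process fluctuation +
#' technical noise.  Archetype parameters (levels, decline onsets, fluctuation
#' kinds) live in the packaged fixture file `extdata/archetypes.yaml` and echo
#' the four dynamic classes seen in tissue: stable high expression, stable
#' lower expression with a gentle drift, early decline, and delayed decline;
#' the declining (differentiation-like) archetypes carry oscillatory
#' fluctuations.  The stored `trend` column makes the additive composition
#' auditable: `value - trend` recovers signal + noise exactly.
#'
#' @param config a [trace_gen_config()].
#' @param archetypes optional archetype parameter list overriding the packaged
#'   fixture.
#' @return long-format `data.frame` with columns `cell_id`, `time_min`,
#'   `value`, `trend`, `x_um`, `y_um`, `z_um`, `label` (archetype index) and
#'   `archetype` (name); the generating config is attached as attribute
#'   `"config"`.
#' @export
gen_population <- function(config = trace_gen_config(), archetypes = NULL) {
  stopifnot(inherits(config, "trace_gen_config"))
  if (is.null(archetypes)) archetypes <- default_archetypes()
  if (sum(config$archetype_mix) <= 0) stop("empty archetype mix")
  set.seed(config$seed)
  times <- seq(0, config$duration, by = config$sampling_interval)
  n <- config$n_cells
  labels <- sample.int(4L, n, replace = TRUE, prob = config$archetype_mix)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- archetypes[[labels[i]]]
    level <- a$level *
      rlnorm(1L, -0.5 * log(1 + config$level_cv^2),
             sqrt(log(1 + config$level_cv^2)))
    trend <- gen_trend(a$trend_kind, times,
                       list(level = level, onset = a$onset,
                            duration = a$duration, drop_frac = a$drop_frac))
    fl_sd <- a$fluct_sd_frac * level
    beta <- if (identical(a$gp_kind, "OUosc")) 2 * pi / a$period_min else 0
    signal <- gen_gp_trace(a$gp_kind, variance = fl_sd^2,
                           lengthscale = a$gp_lengthscale,
                           frequency = beta, times = times)
    value <- add_technical_noise(trend + signal,
                                 config$noise_fraction * fl_sd)
    y0 <- runif(1L, a$y_range[1L], a$y_range[2L])
    ydrift <- if (a$trend_kind == "declining")
      seq(0, runif(1L, 10, 30), length.out = length(times)) else 0
    out[[i]] <- data.frame(
      cell_id = sprintf("cell_%03d", i), time_min = times, value = value,
      trend = trend,
      x_um = runif(1L, 0, 200) + cumsum(rnorm(length(times), 0, 1)),
      y_um = y0 + ydrift + cumsum(rnorm(length(times), 0, 0.5)),
      z_um = runif(1L, 5, 40),
      label = labels[i], archetype = a$name)
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- config
  res
}

#' Generate paired snapshot intensity and concentration tables
#'
#' Nuclear concentrations are drawn from a lognormal distribution with the
#' configured mean and SD; intensities are `concentration / true_scale` plus
#' optional measurement noise; centroids are uniform over the spatial extent.
#' The two tables are paired (same cells), the fixture for quantile-quantile
#' intensity-to-concentration calibration.
#'
#' @param config a [snapshot_gen_config()].
#' @return list with `intensity` (`cell_id`, `x_um`, `y_um`, `intensity`) and
#'   `concentration` (`cell_id`, `concentration_nM`) data frames.
#' @export
gen_snapshot <- function(config = snapshot_gen_config()) {
  stopifnot(inherits(config, "snapshot_gen_config"))
  set.seed(config$seed)
  cv2 <- (config$concentration_sd / config$concentration_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(config$concentration_mean) - sdlog^2 / 2
  conc <- rlnorm(config$n_cells, meanlog, sdlog)
  intensity <- conc / config$true_scale
  if (config$intensity_noise_sd > 0)
    intensity <- pmax(intensity +
                        rnorm(config$n_cells, 0, config$intensity_noise_sd), 0)
  ids <- sprintf("nuc_%04d", seq_len(config$n_cells))
  list(
    intensity = data.frame(cell_id = ids,
                           x_um = runif(config$n_cells, 0, config$spatial_extent),
                           y_um = runif(config$n_cells, 0, config$spatial_extent),
                           intensity = intensity),
    concentration = data.frame(cell_id = ids, concentration_nM = conc))
}

## shared FCS model: two-component 3D diffusion with triplet state
fcs_model <- function(lag_s, N, frac_fast, tau_fast, tau_slow,
                      triplet_frac, tau_triplet, structure_param = 5) {
  diff_term <- function(tau_d)
    1 / ((1 + lag_s / tau_d) * sqrt(1 + lag_s / (structure_param^2 * tau_d)))
  trip <- if (triplet_frac > 0)
    1 + triplet_frac / (1 - triplet_frac) * exp(-lag_s / tau_triplet)
  else rep(1, length(lag_s))
  (1 / N) * trip * (frac_fast * diff_term(tau_fast) +
                      (1 - frac_fast) * diff_term(tau_slow))
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Standard two-component 3D-diffusion autocorrelation with a triplet factor;
#' the zero-lag amplitude is `1 / (N (1 - triplet_frac))`, inversely
#' proportional to the number of molecules in the confocal volume.
#'
#' @param lag_s lag times in seconds (positive, increasing).
#' @param N_molecules mean number of molecules in the effective volume.
#' @param frac_fast fraction of the fast diffusion component, in `[0, 1]`.
#' @param tau_fast,tau_slow diffusion times (s) of the two components.
#' @param triplet_frac triplet fraction in `[0, 1)`.
#' @param tau_triplet triplet relaxation time (s).
#' @param structure_param axial-to-lateral ratio of the confocal volume.
#' @param noise_sd SD of additive Gaussian noise on G.
#' @return `data.frame` with columns `lag_s`, `G`.
#' @export
gen_fcs_curve <- function(lag_s, N_molecules, frac_fast = 0.5,
                          tau_fast = 1e-4, tau_slow = 1e-3,
                          triplet_frac = 0.15, tau_triplet = 5e-6,
                          structure_param = 5, noise_sd = 0) {
  stopifnot(all(lag_s > 0), !is.unsorted(lag_s), N_molecules > 0,
            tau_fast > 0, tau_slow > 0, tau_triplet > 0)
  if (frac_fast < 0 || frac_fast > 1) stop("invalid fast fraction")
  if (triplet_frac < 0 || triplet_frac >= 1) stop("invalid triplet fraction")
  G <- fcs_model(lag_s, N_molecules, frac_fast, tau_fast, tau_slow,
                 triplet_frac, tau_triplet, structure_param)
  if (noise_sd > 0) G <- G + rnorm(length(G), 0, noise_sd)
  data.frame(lag_s = lag_s, G = G)
}

#' Write traces as long-format CSV with a YAML sidecar
#'
#' @param traces long-format data frame from [gen_population()].
#' @param path output CSV path; the sidecar is written to `<path>.yaml`.
#' @export
write_traces_csv <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  cfg <- attr(traces, "config")
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), paste0(path, ".yaml"))
  invisible(path)
}

#' Read traces written by [write_traces_csv()]
#' @param path CSV path.
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar))
    attr(df, "config") <- yaml::read_yaml(sidecar)
  df
}
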