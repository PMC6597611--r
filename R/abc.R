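## Rejection ABC parameterisation of the autorepression model ----------------
##
## Priors encode biophysical bounds: log-uniform transcription (0.1-60/min)
## and translation (0.5-40/min) rates, uniform repression threshold
## (0-120,000 molecules), delay (5-40 min) and Hill coefficient (2-6);
## degradation rates are fixed from measured 30-min (mRNA) and 90-min
## (protein) half-lives.  Samples are accepted when the summarised model
## output falls in the experimentally observed window (mean protein 55,000-
## 65,000 molecules, relative SD above 0.05).

#' Prior specification
#'
#' @param alpha_m_bounds,alpha_p_bounds log-uniform bounds (1/min).
#' @param P0_bounds uniform bounds (molecules).
#' @param tau_bounds uniform bounds (min).
#' @param hill_n_bounds uniform bounds.
#' @param mu_m,mu_p fixed degradation rates (1/min).
#' @export
prior_spec <- function(alpha_m_bounds = c(0.1, 60),
                       alpha_p_bounds = c(0.5, 40),
                       P0_bounds = c(0, 120000),
                       tau_bounds = c(5, 40),
                       hill_n_bounds = c(2, 6),
                       mu_m = log(2) / 30, mu_p = log(2) / 90) {
  structure(list(alpha_m_bounds = alpha_m_bounds,
                 alpha_p_bounds = alpha_p_bounds, P0_bounds = P0_bounds,
                 tau_bounds = tau_bounds, hill_n_bounds = hill_n_bounds,
                 mu_m = mu_m, mu_p = mu_p),
            class = "prior_spec")
}

#' Acceptance window on summary statistics
#'
#' @param mean_low,mean_high accepted range of mean protein number.
#' @param min_relative_sd lower bound on the relative SD of expression.
#' @export
acceptance_window <- function(mean_low = 55000, mean_high = 65000,
                              min_relative_sd = 0.05) {
  stopifnot(mean_low < mean_high, min_relative_sd >= 0)
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 min_relative_sd = min_relative_sd),
            class = "acceptance_window")
}

#' Draw independent samples from the prior
#'
#' Log-uniform marginals are drawn as `exp(uniform(log bounds))`.
#'
#' @param n number of samples.
#' @param prior a [prior_spec()].
#' @param seed optional integer seed.
#' @return data frame with columns `alpha_m`, `alpha_p`, `mu_m`, `mu_p`,
#'   `P0`, `hill_n`, `tau`.
#' @export
sample_prior <- function(n, prior = prior_spec(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    alpha_m = exp(runif(n, log(prior$alpha_m_bounds[1L]),
                        log(prior$alpha_m_bounds[2L]))),
    alpha_p = exp(runif(n, log(prior$alpha_p_bounds[1L]),
                        log(prior$alpha_p_bounds[2L]))),
    mu_m = prior$mu_m, mu_p = prior$mu_p,
    P0 = runif(n, prior$P0_bounds[1L], prior$P0_bounds[2L]),
    hill_n = runif(n, prior$hill_n_bounds[1L], prior$hill_n_bounds[2L]),
    tau = runif(n, prior$tau_bounds[1L], prior$tau_bounds[2L]))
}

row_params <- function(samples, i) {
  model_parameters(alpha_m = samples$alpha_m[i], alpha_p = samples$alpha_p[i],
                   mu_m = samples$mu_m[i], mu_p = samples$mu_p[i],
                   P0 = samples$P0[i], hill_n = samples$hill_n[i],
                   tau = samples$tau[i])
}

abc_summaries <- function(samples, backend, config) {
  n <- nrow(samples)
  mean_p <- numeric(n); rel_sd <- numeric(n)
  for (i in seq_len(n)) {
    p <- row_params(samples, i)
    if (backend == "lna") {
      ss <- steady_state(p)
      mean_p[i] <- ss$protein
      rel_sd[i] <- if (ss$protein > 0)
        sqrt(lna_variance(p)) / ss$protein else 0
    } else {
      sim <- simulate_cle(p, config)
      es <- expression_stats(sim$protein)
      mean_p[i] <- es$mean_protein
      rel_sd[i] <- es$relative_sd
    }
  }
  data.frame(mean_protein = mean_p, relative_sd = rel_sd)
}

#' Rejection ABC
#'
#' Computes summary statistics for every prior sample and accepts those whose
#' mean protein level and relative SD fall inside the acceptance window.  Two
#' summary backends are available: `"cle"` simulates an ensemble of delayed-
#' Langevin traces per sample (the reference route, expensive), `"lna"` uses
#' the deterministic steady state for the mean and the integrated linear-
#' noise spectrum for the variance (fast; agrees with the stochastic
#' summaries away from strongly nonlinear regimes and is recorded in the
#' provenance).
#'
#' @param samples prior samples from [sample_prior()].
#' @param window an [acceptance_window()].
#' @param backend `"lna"` or `"cle"`.
#' @param config [simulation_config()] used by the `"cle"` backend.
#' @return list of class `posterior_set`: `samples` (accepted parameter rows
#'   with their summaries), `n_total`, `n_accepted`, `acceptance_rate`,
#'   `backend`, `window`; zero acceptances yield an empty `samples` table
#'   (with a warning), never a silent failure.
#' @export
abc_reject <- function(samples, window = acceptance_window(),
                       backend = c("lna", "cle"),
                       config = simulation_config()) {
  backend <- match.arg(backend)
  stopifnot(inherits(window, "acceptance_window"))
  sm <- abc_summaries(samples, backend, config)
  ok <- sm$mean_protein >= window$mean_low &
    sm$mean_protein <= window$mean_high &
    sm$relative_sd > window$min_relative_sd
  accepted <- cbind(samples[ok, , drop = FALSE], sm[ok, , drop = FALSE])
  rownames(accepted) <- NULL
  if (!any(ok)) warning("empty posterior: no prior sample was accepted")
  structure(list(samples = accepted, n_total = nrow(samples),
                 n_accepted = sum(ok), acceptance_rate = mean(ok),
                 backend = backend, window = window),
            class = "posterior_set")
}

lna_peak_period_h <- function(params,
                              frequencies = seq(1 / 7500, 1 / 60,
                                                by = 1 / 7500)) {
  ps <- lna_power_spectrum(params, frequencies)
  fpk <- ps$frequencies[which.max(ps$power)]
  1 / fpk / 60
}

posterior_coherence <- function(params) {
  coherence(lna_power_spectrum(params,
                               seq(1 / 7500, 1 / 30, by = 1 / 7500)))
}

#' Posterior predictions of dynamic statistics
#'
#' For each accepted parameter sample, computes one of: the mean Hilbert
#' period of a single equilibrated 12-h Langevin trace (resampled at the
#' experimental 15-min interval before phase extraction), the relative SD of
#' expression over the full observation window (pooled over a small ensemble
#' of traces), the linear-noise coherence, or the mean level.  Samples for
#' which the statistic is undefined (e.g. fewer than two phase resets) are
#' excluded and counted.
#'
#' @param posterior a `posterior_set`.
#' @param statistic one of `"period"`, `"relative_sd"`, `"coherence"`,
#'   `"mean"`.
#' @param sampling_interval resampling interval (min) for period extraction.
#' @param n_traces_sd traces per sample for the `"relative_sd"` route.
#' @param t_obs_period duration (min) of the period-extraction trace.
#' @return list with `values` (per-sample statistics), `mean`, `sd`,
#'   `n_excluded`.
#' @export
posterior_predict <- function(posterior,
                              statistic = c("period", "relative_sd",
                                            "coherence", "mean"),
                              sampling_interval = 15, n_traces_sd = 10L,
                              t_obs_period = 720) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(posterior, "posterior_set"))
  sm <- posterior$samples
  if (!nrow(sm)) stop("empty posterior")
  vals <- numeric(nrow(sm))
  for (i in seq_len(nrow(sm))) {
    p <- row_params(sm, i)
    vals[i] <- switch(statistic,
      period = {
        cfg <- simulation_config(t_obs = t_obs_period, n_traces = 1L)
        sim <- simulate_cle(p, cfg)
        keep <- seq(1L, length(sim$times), by = as.integer(sampling_interval))
        hilbert_period(sim$protein[keep, 1L], sim$times[keep])
      },
      relative_sd = {
        cfg <- simulation_config(n_traces = n_traces_sd)
        expression_stats(simulate_cle(p, cfg)$protein)$relative_sd
      },
      coherence = posterior_coherence(p)$coherence,
      mean = steady_state(p)$protein)
  }
  ok <- is.finite(vals)
  list(values = vals[ok], mean = mean(vals[ok]),
       sd = if (sum(ok) > 1L) sd(vals[ok]) else 0,
       n_excluded = sum(!ok))
}

#' Coherence response to degradation-rate changes
#'
#' Recomputes the oscillation coherence for every posterior sample over grids
#' of protein and mRNA degradation rates: linear-noise coherence for the
#' stochastic model, and the binary Hopf-instability indicator for the
#' deterministic model.  Returns per-sample response curves along the protein
#' grid (at each sample's own mRNA rate) and posterior-mean heatmaps over the
#' full grid.
#'
#' @param posterior a `posterior_set`.
#' @param mu_p_grid,mu_m_grid degradation-rate grids (1/min).
#' @param max_samples cap on posterior samples used (for tractable grids).
#' @return list with `curves` (matrix sample x mu_p), `stochastic_heatmap`
#'   and `deterministic_heatmap` (mu_m x mu_p posterior means), and the
#'   grids.
#' @export
degradation_response <- function(posterior,
                                 mu_p_grid = log(2) / c(360, 180, 120, 90,
                                                        60, 45, 30, 15),
                                 mu_m_grid = log(2) / c(60, 45, 30, 20, 15),
                                 max_samples = 200L) {
  stopifnot(inherits(posterior, "posterior_set"), all(mu_p_grid > 0),
            all(mu_m_grid > 0))
  sm <- posterior$samples
  if (!nrow(sm)) stop("empty posterior")
  if (nrow(sm) > max_samples) sm <- sm[seq_len(max_samples), ]
  nsm <- nrow(sm)
  curves <- matrix(NA_real_, nsm, length(mu_p_grid))
  for (i in seq_len(nsm)) for (j in seq_along(mu_p_grid)) {
    p <- row_params(sm, i); p$mu_p <- mu_p_grid[j]
    curves[i, j] <- posterior_coherence(p)$coherence
  }
  sto <- det <- matrix(NA_real_, length(mu_m_grid), length(mu_p_grid))
  for (a in seq_along(mu_m_grid)) for (b in seq_along(mu_p_grid)) {
    cs <- numeric(nsm); ds <- numeric(nsm)
    for (i in seq_len(nsm)) {
      p <- row_params(sm, i)
      p$mu_m <- mu_m_grid[a]; p$mu_p <- mu_p_grid[b]
      cs[i] <- posterior_coherence(p)$coherence
      ds[i] <- as.numeric(is_oscillatory_deterministic(p))
    }
    sto[a, b] <- mean(cs); det[a, b] <- mean(ds)
  }
  list(curves = curves, mu_p_grid = mu_p_grid, mu_m_grid = mu_m_grid,
       stochastic_heatmap = sto, deterministic_heatmap = det)
}

classify_dynamics <- function(params, coherence_min = 0.1,
                              period_max_h = 10) {
  ch <- posterior_coherence(params)$coherence
  per <- lna_peak_period_h(params)
  list(coherence = ch, period_h = per,
       aperiodic = ch < coherence_min || per > period_max_h)
}

#' Likelihood of single-parameter changes to induce oscillations
#'
#' Identifies aperiodic posterior samples (linear-noise coherence below 0.1
#' or spectral-peak period above 10 h), applies a +/-50% change to each model
#' parameter in turn, and counts conversions to oscillatory behaviour:
#' coherence above 0.1 and a spectral-peak period below 5 h, both evaluated
#' on the analytic linear-noise spectrum so the classification is
#' deterministic.  Per-perturbation conversion likelihoods
#' `L = N_osc / N_steady` are normalised to sum to one.
#'
#' @param posterior a `posterior_set`.
#' @param perturbation fractional change (default 0.5).
#' @param parameters parameters to perturb.
#' @return list with `table` (data frame: parameter, direction, n_converted,
#'   likelihood, normalised_likelihood), `n_steady`, `n_samples`.
#' @export
oscillation_induction_likelihood <- function(posterior, perturbation = 0.5,
                                             parameters = c("alpha_m",
                                                            "alpha_p",
                                                            "mu_m", "mu_p",
                                                            "P0", "hill_n",
                                                            "tau")) {
  stopifnot(inherits(posterior, "posterior_set"))
  sm <- posterior$samples
  if (!nrow(sm)) stop("empty posterior")
  base <- lapply(seq_len(nrow(sm)), function(i)
    classify_dynamics(row_params(sm, i)))
  steady_idx <- which(vapply(base, `[[`, logical(1L), "aperiodic"))
  if (!length(steady_idx)) stop("no aperiodic posterior samples (N_steady = 0)")
  rows <- list()
  for (par in parameters) for (dir in c(1 + perturbation, 1 - perturbation)) {
    n_osc <- 0L
    for (i in steady_idx) {
      p <- row_params(sm, i)
      p[[par]] <- p[[par]] * dir
      cd <- classify_dynamics(p)
      if (cd$coherence > 0.1 && cd$period_h < 5) n_osc <- n_osc + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = par,
      direction = if (dir > 1) "increase" else "decrease",
      n_converted = n_osc,
      likelihood = n_osc / length(steady_idx))
  }
  tab <- do.call(rbind, rows)
  tot <- sum(tab$likelihood)
  tab$normalised_likelihood <- if (tot > 0) tab$likelihood / tot else 0
  list(table = tab, n_steady = length(steady_idx), n_samples = nrow(sm))
}

#' Posterior mean-variance prediction under repression-threshold scaling
#'
#' Scales the repression threshold of every posterior sample from 10% to 200%
#' of its value and records the posterior-predicted mean level (steady state)
#' and expression variance (integrated linear-noise spectrum) at each
#' scaling, together with SD bands, plus the correlation between predicted
#' mean and variance across the scan.
#'
#' @param posterior a `posterior_set`.
#' @param scalings scaling factors applied to `P0`.
#' @param max_samples cap on posterior samples used.
#' @return list with `table` (scaling, mean_level, sd_level, mean_variance,
#'   sd_variance) and `correlation`.
#' @export
mean_variance_prediction <- function(posterior,
                                     scalings = seq(0.1, 2, by = 0.1),
                                     max_samples = 500L) {
  stopifnot(inherits(posterior, "posterior_set"))
  sm <- posterior$samples
  if (!nrow(sm)) stop("empty posterior")
  if (nrow(sm) > max_samples) sm <- sm[seq_len(max_samples), ]
  rows <- lapply(scalings, function(sc) {
    lev <- numeric(nrow(sm)); va <- numeric(nrow(sm))
    for (i in seq_len(nrow(sm))) {
      p <- row_params(sm, i)
      p$P0 <- p$P0 * sc
      lev[i] <- steady_state(p)$protein
      va[i] <- lna_variance(p)
    }
    data.frame(scaling = sc, mean_level = mean(lev), sd_level = sd(lev),
               mean_variance = mean(va), sd_variance = sd(va))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       correlation = cor(tab$mean_level, tab$mean_variance))
}
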