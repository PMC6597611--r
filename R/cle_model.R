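## Delayed stochastic model of transcriptional autorepression ----------------
##
## mRNA M and protein P evolve under delayed chemical Langevin dynamics:
##   dM/dt = -mu_m M + alpha_m G(P(t - tau)) + sqrt(mu_m M + alpha_m G) xi_m
##   dP/dt = -mu_p P + alpha_p M             + sqrt(mu_p P + alpha_p M) xi_p
## with Hill repression G(P) = 1 / (1 + (P/P0)^n).  The module provides the
## Euler-Maruyama simulator (compiled), the deterministic delay limit, the
## steady state, the analytic linear-noise power spectrum of protein
## fluctuations, and a Hopf-bifurcation classifier of the deterministic model.

#' Model parameters of the autorepression circuit
#'
#' @param alpha_m basal transcription rate (1/min).
#' @param alpha_p translation rate per mRNA (1/min).
#' @param mu_m mRNA degradation rate (1/min); default from a 30-min half-life.
#' @param mu_p protein degradation rate (1/min); default from a 90-min
#'   half-life.
#' @param P0 repression threshold (molecules): protein level halving
#'   transcription.
#' @param hill_n Hill coefficient (steepness of autorepression).
#' @param tau transcriptional delay (min).
#' @return list of class `model_parameters`.
#' @export
model_parameters <- function(alpha_m, alpha_p, mu_m = log(2) / 30,
                             mu_p = log(2) / 90, P0, hill_n, tau) {
  stopifnot(alpha_m > 0, alpha_p > 0, mu_m > 0, mu_p > 0, P0 > 0,
            hill_n >= 1, tau >= 0)
  structure(list(alpha_m = alpha_m, alpha_p = alpha_p, mu_m = mu_m,
                 mu_p = mu_p, P0 = P0, hill_n = hill_n, tau = tau),
            class = "model_parameters")
}

#' Simulation settings
#'
#' @param dt Euler step (min).
#' @param t_eq equilibration time discarded from every trace (min).
#' @param t_obs observation window retained for summary statistics (min).
#' @param n_traces number of traces per parameter point.
#' @param M_init,P_init initial molecule numbers (`P_init = NULL` uses `P0`).
#' @export
simulation_config <- function(dt = 1, t_eq = 1000, t_obs = 7500,
                              n_traces = 200, M_init = 10, P_init = NULL) {
  stopifnot(dt > 0, t_eq >= 0, t_obs > 0, n_traces >= 1)
  if (abs(t_eq / dt - round(t_eq / dt)) > 1e-8 ||
      abs(t_obs / dt - round(t_obs / dt)) > 1e-8)
    stop("t_eq and t_obs must be multiples of dt")
  structure(list(dt = dt, t_eq = t_eq, t_obs = t_obs,
                 n_traces = as.integer(n_traces),
                 M_init = M_init, P_init = P_init),
            class = "simulation_config")
}

#' Hill repression factor
#'
#' `G(P) = 1 / (1 + (P/P0)^n)`, the fraction of maximal transcription at
#' protein level `P`; equals 1/2 at the repression threshold.
#'
#' @param P protein level (molecules), non-negative.
#' @param P0 repression threshold.
#' @param hill_n Hill coefficient.
#' @export
hill_repression <- function(P, P0, hill_n) {
  if (any(P < 0)) stop("negative protein level")
  1 / (1 + (P / P0)^hill_n)
}

## dG/dP, needed for the linearisation
hill_derivative <- function(P, P0, hill_n) {
  r <- (P / P0)^hill_n
  -hill_n * r / (P * (1 + r)^2)
}

#' Simulate the delayed chemical Langevin model
#'
#' Euler-Maruyama integration at step `dt` with multiplicative noise
#' amplitudes `sqrt(mu_m M + alpha_m G)` and `sqrt(mu_p P + alpha_p M)`.
#' Transcription is inhibited for `t < tau` (no transcription events initiated
#' at negative times) and the delay is rounded to the nearest multiple of
#' `dt`.  The first `t_eq` minutes are discarded.  Negative excursions are
#' clipped at zero and counted per trace (attribute `"n_clipped"`); a warning
#' is emitted when clipping is frequent, which indicates too large a step.
#'
#' @param params a [model_parameters()].
#' @param config a [simulation_config()].
#' @param stochastic set `FALSE` to switch the noise terms off (the
#'   deterministic Euler limit).
#' @param keep_equilibration keep the equilibration phase in the output.
#' @return list with `times` (min, observation window starting at 0), `mrna`
#'   and `protein` matrices (time x trace).
#' @export
simulate_cle <- function(params, config = simulation_config(),
                         stochastic = TRUE, keep_equilibration = FALSE) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(config, "simulation_config"))
  P_init <- if (is.null(config$P_init)) params$P0 else config$P_init
  n_steps <- as.integer(round((config$t_eq + config$t_obs) / config$dt))
  tau_steps <- as.integer(round(params$tau / config$dt))
  sim <- cle_simulate_cpp(params$alpha_m, params$alpha_p, params$mu_m,
                          params$mu_p, params$P0, params$hill_n, tau_steps,
                          config$dt, n_steps, config$n_traces,
                          config$M_init, P_init, stochastic)
  times <- seq(0, n_steps) * config$dt
  keep <- if (keep_equilibration) seq_along(times) else
    which(times >= config$t_eq)
  res <- list(times = times[keep] - if (keep_equilibration) 0 else config$t_eq,
              mrna = sim$mrna[keep, , drop = FALSE],
              protein = sim$protein[keep, , drop = FALSE])
  attr(res, "n_clipped") <- sim$n_clipped
  if (mean(sim$n_clipped) > 0.01 * n_steps)
    warning("frequent negativity clipping; consider a smaller dt")
  res
}

#' Deterministic limit of the delay model
#'
#' Euler integration of the delay differential system with the noise terms
#' removed, using the same initial conditions, transcription-inhibition
#' convention and step size as [simulate_cle()].
#'
#' @inheritParams simulate_cle
#' @return list with `times`, `mrna`, `protein` (vectors).
#' @export
simulate_deterministic <- function(params, config = simulation_config(),
                                   keep_equilibration = FALSE) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(config, "simulation_config"))
  dt <- config$dt
  P_init <- if (is.null(config$P_init)) params$P0 else config$P_init
  n_steps <- as.integer(round((config$t_eq + config$t_obs) / dt))
  tau_steps <- as.integer(round(params$tau / dt))
  m <- numeric(n_steps + 1L); p <- numeric(n_steps + 1L)
  m[1L] <- config$M_init; p[1L] <- P_init
  for (i in seq_len(n_steps)) {
    trans <- if (i - 1L >= tau_steps)
      params$alpha_m * hill_repression(p[i - tau_steps], params$P0,
                                       params$hill_n) else 0
    mn <- m[i] + dt * (trans - params$mu_m * m[i])
    pn <- p[i] + dt * (params$alpha_p * m[i] - params$mu_p * p[i])
    m[i + 1L] <- max(mn, 0)
    p[i + 1L] <- max(pn, 0)
  }
  times <- seq(0, n_steps) * dt
  keep <- if (keep_equilibration) seq_along(times) else
    which(times >= config$t_eq)
  list(times = times[keep] - if (keep_equilibration) 0 else config$t_eq,
       mrna = m[keep], protein = p[keep])
}

#' Steady state of the deterministic model
#'
#' Solves `mu_m M = alpha_m G(P)` and `mu_p P = alpha_p M`.  Substitution
#' gives a single monotone equation `P = c G(P)` with `c = alpha_m alpha_p /
#' (mu_m mu_p)`, which has a unique positive root found by bracketed search.
#'
#' @param params a [model_parameters()].
#' @param tol relative residual tolerance.
#' @return list with `mrna` and `protein` steady-state values.
#' @export
steady_state <- function(params, tol = 1e-12) {
  cc <- params$alpha_m * params$alpha_p / (params$mu_m * params$mu_p)
  f <- function(P) P - cc * hill_repression(P, params$P0, params$hill_n)
  root <- uniroot(f, c(0, cc), tol = tol * max(cc, 1))$root
  Ms <- params$alpha_m * hill_repression(root, params$P0, params$hill_n) /
    params$mu_m
  list(mrna = Ms, protein = root)
}

#' Analytic linear-noise power spectrum of protein fluctuations
#'
#' The delayed Langevin system is linearised about the steady state (the Hill
#' function enters via its slope `G'(P*)`, the delay via `exp(-i omega tau)`
#' in the characteristic denominator).  Fourier transforming the linearised
#' equations with white-noise loadings `2 mu_m M*` and `2 mu_p P*` gives the
#' protein spectral density
#' \deqn{S(\omega) = \frac{\alpha_p^2\, 2\mu_m M^* + (\omega^2 + \mu_m^2)\,
#'   2\mu_p P^*}{\left|(i\omega+\mu_m)(i\omega+\mu_p) -
#'   \alpha_m\alpha_p G'(P^*) e^{-i\omega\tau}\right|^2}.}
#' The returned one-sided density in ordinary frequency `f` (1/min) is
#' `2 S(2 pi f)`, so its integral over `f >= 0` is the stationary variance.
#'
#' @param params a [model_parameters()].
#' @param frequencies sorted frequency grid (1/min); default the DFT
#'   frequencies of a 7500-min window up to 0.02/min.
#' @return object of class `power_spectrum` (see [coherence()]).
#' @export
lna_power_spectrum <- function(params,
                               frequencies = seq(0, 0.02, by = 1 / 7500)) {
  if (is.unsorted(frequencies)) stop("frequency grid must be sorted")
  ss <- steady_state(params)
  Gp <- hill_derivative(ss$protein, params$P0, params$hill_n)
  omega <- 2 * pi * frequencies
  dm <- complex(real = params$mu_m, imaginary = omega)
  dp <- complex(real = params$mu_p, imaginary = omega)
  Delta <- dm * dp - params$alpha_m * params$alpha_p * Gp *
    exp(complex(imaginary = -omega * params$tau))
  num <- params$alpha_p^2 * 2 * params$mu_m * ss$mrna +
    (omega^2 + params$mu_m^2) * 2 * params$mu_p * ss$protein
  power <- 2 * num / Mod(Delta)^2
  new_power_spectrum(frequencies, power)
}

#' Stationary protein variance under the linear noise approximation
#'
#' Integrates the one-sided spectrum of [lna_power_spectrum()] over frequency
#' with an analytic `1/f^2` tail correction beyond the grid.
#'
#' @param params a [model_parameters()].
#' @param f_max upper integration frequency (1/min).
#' @param n_grid number of grid points.
#' @export
lna_variance <- function(params, f_max = 0.25, n_grid = 3000L) {
  freq <- seq(0, f_max, length.out = n_grid)
  ps <- lna_power_spectrum(params, freq)
  ss <- steady_state(params)
  ## tail: S -> 2 * 2 mu_p P* / omega^2  for omega >> rates
  tail_corr <- params$mu_p * ss$protein / (pi^2 * f_max)
  trapz(ps$frequencies, ps$power) + tail_corr
}

#' Hopf-instability test of the deterministic delay model
#'
#' The linearisation about the steady state has characteristic equation
#' `(lambda + mu_m)(lambda + mu_p) + k exp(-lambda tau) = 0` with
#' `k = alpha_m alpha_p |G'(P*)| > 0`.  A pair of roots crosses the imaginary
#' axis iff `k > mu_m mu_p`, at frequency `omega_c` solving
#' `(omega^2 + mu_m^2)(omega^2 + mu_p^2) = k^2`, and the steady state is
#' unstable (sustained oscillations) iff additionally `tau` exceeds the
#' critical delay `theta / omega_c` where
#' `theta = atan2(omega_c (mu_m + mu_p), omega_c^2 - mu_m mu_p)`.
#'
#' @param params a [model_parameters()].
#' @return `TRUE` if the deterministic model oscillates (unstable steady
#'   state), else `FALSE`.
#' @export
is_oscillatory_deterministic <- function(params) {
  ss <- steady_state(params)
  k <- params$alpha_m * params$alpha_p *
    abs(hill_derivative(ss$protein, params$P0, params$hill_n))
  mm <- params$mu_m; mp <- params$mu_p
  if (k <= mm * mp) return(FALSE)
  disc <- sqrt((mm^2 - mp^2)^2 + 4 * k^2)
  w2 <- (-(mm^2 + mp^2) + disc) / 2
  if (w2 <= 0) return(FALSE)
  wc <- sqrt(w2)
  theta <- atan2(wc * (mm + mp), w2 - mm * mp)
  if (theta < 0) theta <- theta + 2 * pi
  params$tau > theta / wc
}
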