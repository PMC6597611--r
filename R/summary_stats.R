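## Summary statistics for model-data comparison ------------------------------

new_power_spectrum <- function(frequencies, power) {
  power <- pmax(power, 0)
  structure(list(frequencies = frequencies, power = power),
            class = "power_spectrum")
}

#' Number of discrete frequency bins spanned by a smoothing window
#'
#' The DFT of an observation window of length `t_obs` has frequency spacing
#' `1 / t_obs`; a smoothing window of total width `width` (1/min) centred on a
#' bin therefore spans `2 * floor(width/2 * t_obs) + 1` bins (7 bins for a
#' 0.001/min window over 7500 min).
#'
#' @param t_obs observation window (min).
#' @param width smoothing window width (1/min).
#' @export
sg_window_bins <- function(t_obs, width = 0.001) {
  as.integer(2L * floor(width / 2 * t_obs) + 1L)
}

#' Ensemble power spectrum of equally sampled traces
#'
#' Per-trace discrete Fourier transform over the observation window, averaged
#' squared magnitudes across traces, then Savitzky-Golay smoothing (polynomial
#' order 3) over a window of the stated frequency width to suppress
#' finite-size ripple.  Trace means are removed before transforming so the
#' zero-frequency bin carries no power.  Powers are one-sided spectral
#' densities: `sum(power) * df` equals the pooled variance (up to smoothing).
#'
#' @param traces numeric matrix (time x trace) or list of equal-length traces.
#' @param dt sampling interval (min).
#' @param sg_width Savitzky-Golay window width in 1/min (0 disables
#'   smoothing).
#' @return a `power_spectrum` with fields `frequencies` (1/min) and `power`.
#' @export
ensemble_power_spectrum <- function(traces, dt = 1, sg_width = 0.001) {
  if (is.list(traces) && !is.data.frame(traces)) {
    n <- unique(lengths(traces))
    if (length(n) != 1L) stop("traces must share one time grid")
    traces <- do.call(cbind, traces)
  }
  traces <- as.matrix(traces)
  n <- nrow(traces)
  if (n < 8L) stop("traces too short for spectral estimation")
  centred <- sweep(traces, 2L, colMeans(traces))
  ft <- mvfft(centred)
  pow <- rowMeans(Mod(ft)^2) * dt / n          # two-sided density
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1L) / (n * dt)
  pow <- pow[seq_len(nf)]
  one_sided <- pow
  interior <- 2L:(if (n %% 2L == 0L) nf - 1L else nf)
  one_sided[interior] <- 2 * pow[interior]
  if (sg_width > 0) {
    w <- sg_window_bins(n * dt, sg_width)
    w <- max(w, 5L)
    if (w >= nf) stop("fewer frequency bins than the smoothing window")
    one_sided <- signal::sgolayfilt(one_sided, p = 3, n = w)
  }
  new_power_spectrum(freq, one_sided)
}

#' Oscillation coherence of a power spectrum
#'
#' Locates the dominant peak among non-zero frequencies, integrates the power
#' in a band of total width 20% of the peak frequency centred on it
#' (trapezoidal rule, band clipped to the available range), and divides by
#' the total area over positive frequencies.  Near 1 for a sharp spectral
#' line, near the band-area fraction for a flat spectrum.
#'
#' @param spectrum a `power_spectrum`.
#' @param band fractional band width (default 0.2).
#' @return list with `coherence`, `peak_frequency` (1/min), `A_max`, `A_tot`.
#' @export
coherence <- function(spectrum, band = 0.2) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$frequencies > 0
  f <- spectrum$frequencies[keep]
  p <- spectrum$power[keep]
  if (!length(f) || all(p == 0)) stop("all-zero spectrum")
  ipk <- which.max(p)
  fpk <- f[ipk]
  lo <- fpk * (1 - band / 2)
  hi <- fpk * (1 + band / 2)
  inb <- f >= lo & f <= hi
  A_tot <- trapz(f, p)
  A_max <- trapz(f[inb], p[inb])
  list(coherence = A_max / A_tot, peak_frequency = fpk,
       A_max = A_max, A_tot = A_tot)
}

#' Mean oscillation period from the Hilbert phase
#'
#' Computes the analytic-signal phase of the (mean-centred) trace, unwraps
#' it, and measures periods as time differences between consecutive
#' descending zero-crossings of the wrapped phase, i.e. passages through
#' `pi + 2 pi k` of the unwrapped phase (troughs); crossing times are linearly
#' interpolated.  The mean interval is returned in hours; `NA` with attribute
#' `"n_crossings"` when fewer than two crossings exist.
#'
#' @param values trace values.
#' @param times sampling times (minutes), uniform grid.
#' @param detrend_mean subtract the trace mean first (default `TRUE`).
#' @return mean period in hours (`NA` if undefined).
#' @export
hilbert_period <- function(values, times, detrend_mean = TRUE) {
  stopifnot(length(values) == length(times))
  if (sd(values) == 0) stop("constant trace has no phase")
  y <- if (detrend_mean) values - mean(values) else values
  phase <- unwrap_phase(Arg(analytic_signal(y)))
  k <- seq(floor(min(phase) / (2 * pi)) - 1L, ceiling(max(phase) / (2 * pi)))
  crossings <- sort(unlist(lapply(pi + 2 * pi * k, function(lev)
    crossing_times(times, phase, lev))))
  if (length(crossings) < 2L) {
    out <- NA_real_
    attr(out, "n_crossings") <- length(crossings)
    return(out)
  }
  mean(diff(crossings)) / 60
}

#' Pooled expression statistics across traces
#'
#' Mean, SD and relative SD (SD/mean) pooled across all traces and all
#' timepoints of the observation window, the summary statistics used for
#' model-data comparison.
#'
#' @param traces numeric matrix (time x trace), vector, or list of traces.
#' @return list with `mean_protein`, `sd_protein`, `relative_sd`.
#' @export
expression_stats <- function(traces) {
  if (is.list(traces) && !is.data.frame(traces)) traces <- unlist(traces)
  x <- as.numeric(traces)
  if (!length(x)) stop("empty input")
  m <- mean(x)
  ## population SD over the pooled sample
  s <- sqrt(mean((x - m)^2))
  list(mean_protein = m, sd_protein = s,
       relative_sd = if (m > 0) s / m else NA_real_)
}

#' Export a power spectrum as a two-column data frame
#' @param x a `power_spectrum`.
#' @param ... unused.
#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(frequency = x$frequencies, power = x$power)
}
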