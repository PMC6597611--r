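## FCS-anchored absolute quantification --------------------------------------

AVOGADRO <- 6.02214076e23

#' Fit a two-component diffusion model with triplet state to an FCS curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the standard 3D
#' Gaussian confocal-volume autocorrelation
#' `G(tau) = (1/N) (1 + T/(1-T) e^{-tau/tau_T})
#'   (f g(tau; tau_fast) + (1-f) g(tau; tau_slow))` with
#' `g(tau; tau_D) = (1 + tau/tau_D)^{-1} (1 + tau/(S^2 tau_D))^{-1/2}`.
#' Initial conditions assume the fast component diffuses 10x faster than the
#' slow one.  The molecule number follows from the amplitude, and the
#' concentration from the effective confocal volume.  When a count-rate
#' trace is supplied, quality-control flags mark low counts per molecule
#' (< 0.5 kHz), high triplet fraction (> 50%) and high bleaching (> 10%).
#'
#' @param curve data frame with `lag_s` and `G` (e.g. [gen_fcs_curve()] or
#'   [read_fcs_csv()]).
#' @param effective_volume_fL effective confocal volume (fL), default 0.57.
#' @param structure_param axial-to-lateral ratio of the confocal volume.
#' @param count_rate_khz optional count-rate trace (kHz) for QC.
#' @return list with `N_molecules`, `concentration_nM`, `params` (named
#'   vector of fitted parameters), `qc` (named logical flags), `fitted` (the
#'   fitted curve on the input lag grid), `fit` (the `nls.lm` object).
#' @export
fit_fcs_autocorrelation <- function(curve, effective_volume_fL = 0.57,
                                    structure_param = 5,
                                    count_rate_khz = NULL) {
  stopifnot(all(c("lag_s", "G") %in% names(curve)),
            effective_volume_fL > 0)
  if (nrow(curve) < 8L) stop("curve shorter than the parameter count")
  lag_s <- curve$lag_s; G <- curve$G
  N0 <- 1 / max(G[1L], 1e-12)
  ## diffusion-time start: lag where G first falls to half its initial value
  half_idx <- which(G <= G[1L] / 2)
  tau_slow0 <- if (length(half_idx)) lag_s[half_idx[1L]] else
    lag_s[ceiling(length(lag_s) / 2)]
  S <- structure_param
  ## unconstrained parameterisation: log for scales, logistic for fractions
  curve_at <- function(par)
    fcs_model(lag_s, exp(par[1L]), stats::plogis(par[2L]),
              exp(par[3L]) / exp(par[4L]), exp(par[3L]),
              stats::plogis(par[5L]), exp(par[6L]), S)
  start <- c(log(N0), 0, log(tau_slow0), log(10), -2, log(5e-6))
  fit <- minpack.lm::nls.lm(start, fn = function(par) G - curve_at(par),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ptol = 1e-12, ftol = 1e-12))
  cf <- fit$par
  N <- exp(cf[1L])
  triplet <- stats::plogis(cf[5L])
  params <- c(N_molecules = N, frac_fast = stats::plogis(cf[2L]),
              tau_fast_s = exp(cf[3L]) / exp(cf[4L]),
              tau_slow_s = exp(cf[3L]),
              triplet_frac = triplet, tau_triplet_s = exp(cf[6L]))
  fitted_curve <- curve_at(cf)
  qc <- c(high_triplet = triplet > 0.5)
  if (!is.null(count_rate_khz)) {
    cpm <- mean(count_rate_khz) / N
    nseg <- length(count_rate_khz)
    bleach <- 1 - mean(tail(count_rate_khz, ceiling(nseg / 10))) /
      mean(head(count_rate_khz, ceiling(nseg / 10)))
    qc <- c(qc, low_cpm = cpm < 0.5, high_bleaching = bleach > 0.1)
  }
  list(N_molecules = unname(N),
       concentration_nM = concentration_from_molecules(N,
                                                       effective_volume_fL),
       params = params, qc = qc, fitted = fitted_curve, fit = fit)
}

#' Convert a molecule number in a volume to a concentration
#' @param n_molecules molecule count.
#' @param volume_fL volume in femtolitres.
#' @return concentration in nM.
#' @export
concentration_from_molecules <- function(n_molecules, volume_fL) {
  stopifnot(n_molecules >= 0, volume_fL > 0)
  n_molecules / (volume_fL * 1e-15 * AVOGADRO) * 1e9
}

#' Molecules per nucleus from a nuclear concentration
#'
#' `N = C * V * N_A` with unit handling; the default nuclear volume is the
#' 523 fL estimate from 3D reconstruction of stained nuclei.
#'
#' @param concentration_nM nuclear concentration (nM).
#' @param nuclear_volume_fL nuclear volume (fL).
#' @export
molecules_per_nucleus <- function(concentration_nM, nuclear_volume_fL = 523) {
  if (any(concentration_nM < 0) || nuclear_volume_fL <= 0)
    stop("inputs must be non-negative (volume positive)")
  concentration_nM * 1e-9 * nuclear_volume_fL * 1e-15 * AVOGADRO
}

#' Quantile-quantile calibration of intensity against concentration
#'
#' Pairs the two distributions on a common 1%-step quantile grid and fits a
#' least-squares line over the middle quantile span (default the 5%-95%
#' quantiles, i.e. the middle 90%); the gradient is the intensity-to-
#' concentration scaling factor.
#'
#' @param intensity sample of background-subtracted intensities.
#' @param concentration sample of FCS-derived concentrations (nM).
#' @param middle central quantile span used for the fit.
#' @return list of class `calibration_model`: `scale` (nM per intensity
#'   unit), `intercept`, `r_squared`, `quantiles` (data frame), `middle`.
#' @export
qq_calibrate <- function(intensity, concentration, middle = 0.90) {
  stopifnot(length(intensity) >= 20L, length(concentration) >= 20L,
            middle > 0, middle <= 1)
  if (sd(intensity) == 0 || sd(concentration) == 0)
    stop("degenerate (constant) distribution")
  probs <- seq(0.01, 0.99, by = 0.01)
  qi <- quantile(intensity, probs, names = FALSE, type = 7)
  qc <- quantile(concentration, probs, names = FALSE, type = 7)
  lo <- (1 - middle) / 2
  keep <- probs >= lo & probs <= 1 - lo
  fit <- lm(qc[keep] ~ qi[keep])
  structure(list(scale = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 quantiles = data.frame(prob = probs, intensity = qi,
                                        concentration = qc),
                 middle = middle),
            class = "calibration_model")
}

#' Apply a calibration model to a snapshot table
#'
#' `concentration = scale * intensity` per cell; negative background-
#' subtracted intensities are clipped to zero and counted.
#'
#' @param cells data frame with an `intensity` column.
#' @param model a `calibration_model`.
#' @return the input with a `concentration_nM` column; the model and clip
#'   count attached as attributes `"calibration"`, `"n_clipped"`.
#' @export
apply_calibration <- function(cells, model) {
  stopifnot(inherits(model, "calibration_model"),
            "intensity" %in% names(cells))
  n_clip <- sum(cells$intensity < 0)
  inten <- pmax(cells$intensity, 0)
  cells$concentration_nM <- model$scale * inten
  attr(cells, "calibration") <- model
  attr(cells, "n_clipped") <- n_clip
  cells
}

#' Nearest-neighbour differences and regional variability
#'
#' Ranks neighbours by centroid distance (ties at the minimum distance all
#' belong to rank 1), records per cell the mean absolute concentration
#' difference to its first-rank neighbours, and summarises per spatial band
#' (split on distance from the ventricle analogue) the COV of concentration.
#'
#' @param cells data frame with `x_um`, `y_um` and a value column.
#' @param value_col column holding the quantity to compare.
#' @param split_at band boundary on `y_um` (um from ventricle); `NULL` for a
#'   single region.
#' @return list with `per_cell` (cell, neighbour difference, band) and
#'   `regional` (band, n, mean value, cov_percent, mean neighbour
#'   difference); single-cell bands are excluded.
#' @export
neighbour_stats <- function(cells, value_col = "concentration_nM",
                            split_at = 50) {
  stopifnot(nrow(cells) >= 2L,
            all(c("x_um", "y_um", value_col) %in% names(cells)))
  v <- cells[[value_col]]
  dmat <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
  diag(dmat) <- Inf
  nn_diff <- vapply(seq_len(nrow(cells)), function(i) {
    dmin <- min(dmat[i, ])
    nbrs <- which(dmat[i, ] <= dmin * (1 + 1e-9))
    mean(abs(v[nbrs] - v[i]))
  }, numeric(1L))
  band <- if (is.null(split_at)) rep("all", nrow(cells)) else
    ifelse(cells$y_um < split_at, sprintf("< %g um", split_at),
           sprintf(">= %g um", split_at))
  per_cell <- data.frame(cell = seq_len(nrow(cells)),
                         neighbour_diff = nn_diff, band = band)
  regional <- do.call(rbind, lapply(split(seq_len(nrow(cells)), band),
                                    function(idx) {
    if (length(idx) < 2L) return(NULL)
    data.frame(band = band[idx[1L]], n = length(idx),
               mean_value = mean(v[idx]),
               cov_percent = 100 * sd(v[idx]) / mean(v[idx]),
               mean_neighbour_diff = mean(nn_diff[idx]))
  }))
  rownames(regional) <- NULL
  list(per_cell = per_cell, regional = regional)
}

#' Read an FCS autocorrelation curve from a two-column CSV
#' @param path CSV with columns `lag_s`, `G`.
#' @export
read_fcs_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("lag_s", "G") %in% names(df)))
  df
}

#' Persist a calibration model as YAML
#' @param model a `calibration_model`.
#' @param path output path.
#' @export
write_calibration_yaml <- function(model, path) {
  yaml::write_yaml(list(scale = model$scale, intercept = model$intercept,
                        r_squared = model$r_squared, middle = model$middle),
                   path)
  invisible(path)
}
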