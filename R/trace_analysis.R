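## Post-detection analytics of single-cell traces ----------------------------

#' Hilbert reconstruction of instantaneous amplitude and phase
#'
#' Computes the analytic signal of a fitted detrended trace (typically the
#' OUosc posterior mean), giving the instantaneous amplitude
#' `A = sqrt(Re z^2 + Im z^2)` and raw phase in `(-pi, pi]`.  The signal is
#' restored to intensity units by summation with the long-term trend, and the
#' amplitude envelope is likewise reported on the intensity scale.
#'
#' @param fitted fitted detrended trace (zero mean).
#' @param trend long-term trend on the original scale, same length.
#' @param times sampling times (min).
#' @return list of class `hilbert_trace`: `times`, `amplitude` (detrended
#'   units), `phase` (radians), `signal` (trend-restored trace),
#'   `amplitude_restored` (`trend + amplitude`).
#' @export
hilbert_reconstruct <- function(fitted, trend, times) {
  stopifnot(length(fitted) == length(trend),
            length(fitted) == length(times))
  if (sd(fitted) == 0) stop("constant input has no instantaneous phase")
  z <- analytic_signal(fitted)
  structure(list(times = times, amplitude = Mod(z), phase = Arg(z),
                 signal = fitted + trend,
                 amplitude_restored = trend + Mod(z)),
            class = "hilbert_trace")
}

phase_crossings <- function(hil, what = c("peak", "trough")) {
  what <- match.arg(what)
  up <- unwrap_phase(hil$phase)
  offset <- if (what == "peak") 0 else pi
  k <- seq(floor((min(up) - offset) / (2 * pi)) - 1L,
           ceiling((max(up) - offset) / (2 * pi)))
  sort(unlist(lapply(offset + 2 * pi * k, function(lev)
    crossing_times(hil$times, up, lev))))
}

#' Peak-to-trough fold changes on the trend-restored signal
#'
#' Peaks are ascending zero-crossings of the instantaneous phase, troughs are
#' descending ones (phase resets); both are evaluated on the trend-restored
#' signal by linear interpolation.  Each peak is paired with its nearest
#' trough in time (ties broken towards the following trough) and the
#' peak-to-trough intensity ratio reported per pair.  On a declining trend
#' the trend itself amplifies the instantaneous drop, which is why fold
#' changes are computed on the signal including the trend.
#'
#' @param hil a [hilbert_reconstruct()] result.
#' @return list of class `fold_change_report`: `pairs` (data frame with
#'   `peak_time`, `trough_time`, `peak_value`, `trough_value`,
#'   `fold_change`), `max_fold_change`, `mean_fold_change`, `n_peaks`,
#'   `n_troughs`; empty (with `NA` summaries) when no crossings exist.
#' @export
peak_trough_fold_changes <- function(hil) {
  stopifnot(inherits(hil, "hilbert_trace"))
  peaks <- phase_crossings(hil, "peak")
  troughs <- phase_crossings(hil, "trough")
  if (!length(peaks) || !length(troughs)) {
    return(structure(list(pairs = data.frame(), max_fold_change = NA_real_,
                          mean_fold_change = NA_real_,
                          n_peaks = length(peaks),
                          n_troughs = length(troughs)),
                     class = "fold_change_report"))
  }
  value_at <- function(t) approx(hil$times, hil$signal, t, rule = 2)$y
  pairs <- do.call(rbind, lapply(peaks, function(pk) {
    d <- abs(troughs - pk)
    ## nearest trough; on a tie prefer the later (following) trough
    cand <- which(d == min(d))
    tr <- troughs[cand[length(cand)]]
    data.frame(peak_time = pk, trough_time = tr,
               peak_value = value_at(pk), trough_value = value_at(tr))
  }))
  pairs$fold_change <- pairs$peak_value / pairs$trough_value
  structure(list(pairs = pairs,
                 max_fold_change = max(pairs$fold_change),
                 mean_fold_change = mean(pairs$fold_change),
                 n_peaks = length(peaks), n_troughs = length(troughs)),
            class = "fold_change_report")
}

#' Amplitude-death summary over time
#'
#' Bins instantaneous amplitudes over time per group, locates the epoch of
#' maximum mean amplitude, and tests each later epoch against it (two-sample
#' test on cell-level amplitudes), quantifying progressive decay of
#' oscillation amplitude.
#'
#' @param amplitudes data frame with columns `cell_id`, `time_min`,
#'   `amplitude` and `group`.
#' @param bin_h epoch width in hours.
#' @param test `"t"` or `"wilcox"`.
#' @return data frame with one row per group x epoch: mean and SD amplitude,
#'   number of cells, and `p_value` versus that group's maximum epoch (`NA`
#'   for the maximum epoch itself and epochs before it).  Groups with fewer
#'   than 3 cells are dropped with a message; all-zero groups are flagged via
#'   the `degenerate` column.
#' @export
amplitude_death <- function(amplitudes, bin_h = 2, test = c("t", "wilcox")) {
  test <- match.arg(test)
  stopifnot(all(c("cell_id", "time_min", "amplitude", "group") %in%
                  names(amplitudes)))
  out <- list()
  for (g in unique(amplitudes$group)) {
    sub <- amplitudes[amplitudes$group == g, ]
    if (length(unique(sub$cell_id)) < 3L) {
      message("group '", g, "' has fewer than 3 cells; excluded")
      next
    }
    sub$epoch <- floor(sub$time_min / (bin_h * 60))
    ## one amplitude per cell per epoch
    agg <- stats::aggregate(amplitude ~ cell_id + epoch, sub, mean)
    epochs <- sort(unique(agg$epoch))
    means <- vapply(epochs, function(e)
      mean(agg$amplitude[agg$epoch == e]), numeric(1L))
    degenerate <- all(agg$amplitude == 0)
    imax <- which.max(means)
    ref <- agg$amplitude[agg$epoch == epochs[imax]]
    for (i in seq_along(epochs)) {
      cur <- agg$amplitude[agg$epoch == epochs[i]]
      p <- NA_real_
      if (!degenerate && i > imax && length(cur) >= 3L) {
        p <- if (test == "t") t.test(cur, ref)$p.value else
          wilcox.test(cur, ref, exact = FALSE)$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, epoch_start_h = epochs[i] * bin_h,
        mean_amplitude = means[i], sd_amplitude = sd(cur),
        n_cells = length(cur), p_value = p, degenerate = degenerate)
    }
  }
  do.call(rbind, out)
}

#' Standardise a trace (z-score)
#'
#' Subtracts the trace mean and divides by the population SD (divisor `n`),
#' so relative shape rather than absolute level drives downstream clustering.
#'
#' @param x numeric trace with positive SD.
#' @export
standardize <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant trace cannot be standardised")
  (x - mean(x)) / s
}

#' Align, truncate and standardise traces for clustering
#'
#' Cells are aligned to start at time 0, truncated to the shortest common
#' length, and cells covering less than `min_coverage` of that window are
#' excluded.
#'
#' @param traces long data frame with `cell_id`, `time_min`, `value`.
#' @param min_coverage minimum fraction of the common window a cell must
#'   cover.
#' @return matrix (cell x time) of standardised traces.
#' @export
align_traces <- function(traces, min_coverage = 0.8) {
  split_tr <- split(traces, traces$cell_id)
  lens <- vapply(split_tr, nrow, integer(1L))
  target <- max(lens)
  keep <- lens >= min_coverage * target
  if (!all(keep))
    message(sum(!keep), " cell(s) below ", min_coverage * 100,
            "% coverage excluded")
  split_tr <- split_tr[keep]
  common <- min(vapply(split_tr, nrow, integer(1L)))
  mat <- t(vapply(split_tr, function(d)
    standardize(d$value[order(d$time_min)][seq_len(common)]),
    numeric(common)))
  rownames(mat) <- names(split_tr)
  mat
}

#' Hierarchical clustering of standardised traces
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage
#' (`ward.D2`, the Ward criterion for Euclidean distances), cut at `k`
#' clusters, with elbow (within-cluster sum of squares) and mean-silhouette
#' diagnostics over a range of cluster numbers.
#'
#' @param mat matrix (cell x time) of standardised traces, e.g. from
#'   [align_traces()].
#' @param k number of clusters.
#' @param k_range cluster numbers scanned for diagnostics.
#' @return list of class `cluster_result`: `labels` (named integer vector),
#'   `hclust`, `diagnostics` (data frame `k`, `wss`, `silhouette`).
#' @export
hcluster <- function(mat, k = 4L, k_range = 2:8) {
  stopifnot(is.matrix(mat), nrow(mat) > k)
  d <- stats::dist(mat)
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  diag_df <- do.call(rbind, lapply(k_range, function(kk) {
    lab <- stats::cutree(hc, k = kk)
    wss <- sum(vapply(split(seq_len(nrow(mat)), lab), function(idx) {
      centred <- scale(mat[idx, , drop = FALSE], scale = FALSE)
      sum(centred^2)
    }, numeric(1L)))
    sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])
    data.frame(k = kk, wss = wss, silhouette = sil)
  }))
  structure(list(labels = labels, hclust = hc, diagnostics = diag_df),
            class = "cluster_result")
}

#' Coefficient of variation over expanding time windows
#'
#' For each stated window length, the COV (`SD/mean * 100`) of all normalised
#' intensity values of one cell within `[0, window]`; windows exceeding the
#' trace duration are omitted with a message.
#'
#' @param values normalised (not standardised) trace.
#' @param times sampling times (min).
#' @param windows_h window lengths in hours.
#' @return data frame with `window_h` and `cov_percent`.
#' @export
cov_over_windows <- function(values, times,
                             windows_h = c(4, 8, 12, 14.25, 17.25)) {
  duration <- max(times) - min(times)
  ok <- windows_h * 60 <= duration + 1e-9
  if (!all(ok))
    message("window(s) ", paste(windows_h[!ok], collapse = ", "),
            " h exceed trace duration; omitted")
  out <- lapply(windows_h[ok], function(w) {
    x <- values[times <= min(times) + w * 60 + 1e-9]
    data.frame(window_h = w, cov_percent = 100 * sd(x) / mean(x))
  })
  do.call(rbind, out)
}

#' Shoulder point of a declining trace
#'
#' On the smoothed trend (squared-exponential GP trend, consistent with the
#' detrending used elsewhere), finds the latest turning point followed by a
#' sustained decline exceeding 50% of the value at that point; returns its
#' time, or `NULL` when no such point exists.
#'
#' @param values trace values.
#' @param times sampling times (min).
#' @param drop_threshold required fractional drop after the turning point.
#' @param trend optional pre-computed trend (skips the GP fit).
#' @export
shoulder_point <- function(values, times, drop_threshold = 0.5,
                           trend = NULL) {
  if (is.null(trend)) trend <- detrend(values, times)$trend
  n <- length(trend)
  ## candidate turning points: samples where the smoothed trend turns from
  ## non-decreasing (including plateaus) to decreasing
  d <- diff(trend)
  cand <- which(c(TRUE, d[-length(d)] >= 0) & d < 0)
  for (i in sort(cand, decreasing = TRUE)) {
    if (min(trend[i:n]) < (1 - drop_threshold) * trend[i])
      return(times[i])
  }
  NULL
}

#' Correct intensities for imaging depth
#'
#' Fits one movie-wide least-squares regression of intensity on z-depth
#' across all cells and timepoints, then shifts each cell's whole trace by
#' `-slope * z_initial`, i.e. corrects it as if the cell sat at z = 0.
#'
#' @param traces long data frame with `cell_id`, `time_min`, `value`, `z_um`.
#' @return the input with a corrected `value` column; regression slope and
#'   intercept attached as attribute `"zfit"`.
#' @export
zdepth_correct <- function(traces) {
  stopifnot(all(c("cell_id", "time_min", "value", "z_um") %in% names(traces)))
  if (length(unique(traces$z_um)) == 1L) {
    message("all cells at identical z; no correction applied")
    attr(traces, "zfit") <- c(slope = 0, intercept = NA_real_)
    return(traces)
  }
  fit <- lm(value ~ z_um, data = traces)
  slope <- unname(coef(fit)[2L])
  for (id in unique(traces$cell_id)) {
    idx <- traces$cell_id == id
    z0 <- traces$z_um[idx][which.min(traces$time_min[idx])]
    traces$value[idx] <- traces$value[idx] - slope * z0
  }
  attr(traces, "zfit") <- c(slope = slope,
                            intercept = unname(coef(fit)[1L]))
  traces
}

#' Descriptive positional summaries of a cell track
#'
#' @param x,y coordinates (um) over time.
#' @return list with `total_distance`, `displacement`, `mean_step`.
#' @export
track_summary <- function(x, y) {
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  list(total_distance = sum(steps),
       displacement = sqrt((x[length(x)] - x[1L])^2 +
                             (y[length(y)] - y[1L])^2),
       mean_step = if (length(steps)) mean(steps) else 0)
}
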