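#' Replace outliers by scaled-MAD rule with linear interpolation
#'
#' Flags samples lying more than `mad_multiplier` scaled median absolute
#' deviations (MAD x 1.4826, the normal-consistency constant) above or below
#' the trace median and replaces each by linear interpolation, in time,
#' between the nearest preceding and following unflagged samples. Flagged
#' samples before the first (after the last) unflagged sample take the
#' nearest unflagged value. Missing samples are untouched and never used for
#' interpolation. When the scaled MAD is zero, any deviation from the median
#' is flagged.
#'
#' @param trace A [signal_trace()] with at least 3 non-missing samples.
#' @param mad_multiplier Positive multiplier (default 6).
#' @return A `signal_trace` on the same grid.
#' @export
replace_outliers <- function(trace, mad_multiplier = 6) {
  stopifnot(inherits(trace, "signal_trace"), mad_multiplier > 0)
  x <- trace$values
  obs <- !is.na(x)
  if (sum(obs) < 3L)
    stop("replace_outliers needs >= 3 non-missing samples", call. = FALSE)
  med <- stats::median(x[obs])
  smad <- stats::mad(x[obs])           # default constant 1.4826
  flagged <- obs & abs(x - med) > mad_multiplier * smad
  if (!any(flagged)) return(trace)
  keep <- obs & !flagged
  if (!any(keep))
    stop("all samples flagged as outliers; degenerate trace", call. = FALSE)
  tt <- trace_times(trace)
  if (sum(keep) == 1L) {
    x[flagged] <- x[keep]
  } else {
    x[flagged] <- stats::approx(tt[keep], x[keep], xout = tt[flagged],
                                rule = 2)$y
  }
  out <- trace
  out$values <- x
  out
}

#' Non-overlapping window averages
#'
#' Averages a trace over consecutive non-overlapping windows aligned to its
#' start (left-closed, right-open). Each output sample is the mean of the
#' non-missing samples in its window, timestamped at the window's left edge;
#' windows with fewer than `min_valid_fraction` valid samples yield `NA`.
#' Trailing samples that do not fill a whole window are dropped, so the
#' output has exactly `floor(duration / window_seconds)` samples.
#'
#' @param trace A [signal_trace()].
#' @param window_seconds Window length in seconds; must be an integer
#'   multiple of the sampling interval and at least one interval.
#' @param min_valid_fraction Minimum fraction of non-missing samples for a
#'   window mean to be emitted (default 0.5).
#' @return A `signal_trace` with `sample_interval = window_seconds`.
#' @export
window_average <- function(trace, window_seconds, min_valid_fraction = 0.5) {
  stopifnot(inherits(trace, "signal_trace"))
  k <- window_seconds / trace$sample_interval
  if (window_seconds < trace$sample_interval)
    stop("window_seconds must be >= the sampling interval", call. = FALSE)
  if (abs(k - round(k)) > 1e-8)
    stop("window_seconds must be an integer multiple of the sampling interval",
         call. = FALSE)
  k <- as.integer(round(k))
  n_win <- length(trace$values) %/% k
  if (n_win < 1L)
    stop("trace shorter than one window", call. = FALSE)
  m <- matrix(trace$values[seq_len(n_win * k)], nrow = k)
  n_valid <- colSums(!is.na(m))
  means <- colSums(m, na.rm = TRUE) / n_valid
  means[n_valid < min_valid_fraction * k] <- NA_real_
  means[n_valid == 0L] <- NA_real_
  signal_trace(means, window_seconds, start_time = trace$start_time,
               channel = trace$channel)
}

#' Per-window ICP pulse amplitude
#'
#' Estimates the cardiac pulse amplitude of the ICP waveform as the
#' peak-to-trough range of the linearly detrended samples in each
#' non-overlapping window (left-edge timestamps, same alignment as
#' [window_average()]). Detrending removes slow drift so only pulsatile
#' excursion is measured; the trend slope comes from neighbouring window
#' means so the pulsation itself cannot tilt it (see Details in the source).
#' The result is always >= 0. Windows with fewer than `min_valid_fraction`
#' valid samples yield `NA`.
#'
#' @param icp_waveform A [signal_trace()] sampled at >= 4 Hz (the cardiac
#'   pulsation must be resolved). For pre-averaged 10-s data supply a
#'   pre-computed amplitude channel instead.
#' @param window_seconds Window length in seconds (default 10).
#' @param min_valid_fraction Validity floor per window (default 0.5).
#' @return A `signal_trace` of amplitudes (mmHg) at `window_seconds`.
#' @export
pulse_amplitude <- function(icp_waveform, window_seconds = 10,
                            min_valid_fraction = 0.5) {
  stopifnot(inherits(icp_waveform, "signal_trace"))
  rate <- 1 / icp_waveform$sample_interval
  if (rate < 4)
    stop("pulse_amplitude needs a waveform sampled at >= 4 Hz; ",
         "supply a pre-averaged amplitude channel for low-rate data",
         call. = FALSE)
  k <- as.integer(round(window_seconds / icp_waveform$sample_interval))
  n_win <- length(icp_waveform$values) %/% k
  if (n_win < 1L) stop("waveform shorter than one window", call. = FALSE)
  m <- matrix(icp_waveform$values[seq_len(n_win * k)], nrow = k)
  idx <- seq_len(k)
  # The trend slope is estimated from neighbouring window means (centred
  # difference; one-sided at the edges): full-window means average the
  # cardiac cycle out almost exactly, whereas any in-window line fit is
  # tilted by the sampled pulsation (a discrete sine is not orthogonal to a
  # line) and overstates the range by several percent. Drift passes through
  # window means exactly, so linear drift is still removed. A trace with a
  # single window falls back to an in-window fit on 1-s sub-bin means.
  wm <- colMeans(m, na.rm = TRUE)
  n_bins <- max(2L, as.integer(round(window_seconds)))
  bin_of <- pmin(ceiling(idx / (k / n_bins)), n_bins)
  bin_center <- vapply(seq_len(n_bins), function(b) mean(idx[bin_of == b]),
                       numeric(1))
  slope_for <- function(j, w) {
    left <- if (j > 1L) wm[j - 1L] else NA_real_
    right <- if (j < n_win) wm[j + 1L] else NA_real_
    if (is.finite(left) && is.finite(right)) return((right - left) / (2 * k))
    if (is.finite(right) && is.finite(wm[j])) return((right - wm[j]) / k)
    if (is.finite(left) && is.finite(wm[j])) return((wm[j] - left) / k)
    bm <- vapply(seq_len(n_bins), function(b)
      mean(w[bin_of == b], na.rm = TRUE), numeric(1))
    bok <- is.finite(bm)
    if (sum(bok) < 2) return(0)
    tc <- bin_center[bok] - mean(bin_center[bok])
    sum(tc * (bm[bok] - mean(bm[bok]))) / sum(tc * tc)
  }
  amp <- vapply(seq_len(n_win), function(j) {
    w <- m[, j]
    ok <- !is.na(w)
    if (sum(ok) < max(2, min_valid_fraction * k)) return(NA_real_)
    r <- w[ok] - slope_for(j, w) * idx[ok]
    max(r) - min(r)
  }, numeric(1))
  signal_trace(amp, window_seconds, start_time = icp_waveform$start_time,
               channel = "amp")
}

#' Derived channel set for one patient
#'
#' Repairs artifacts on the raw HR, ABP and ICP traces with
#' [replace_outliers()] (trend indices downstream receive no further outlier
#' handling), then builds the aligned channel set used by the rest of the
#' pipeline: 10-s means of ABP and ICP, the 10-s ICP pulse amplitude (AMP),
#' CPP = ABP - ICP at 10 s, and 1-per-minute ABP, ICP and HR. Gaps propagate:
#' missing windows stay missing and are never interpolated.
#'
#' If the input is waveform-rate (>= 4 Hz), AMP is computed from the repaired
#' ICP waveform; if the input is already at 10-s resolution, the record's
#' `amp` channel is used, or AMP is all-missing (with a warning) when absent.
#'
#' @param record A [patient_record()].
#' @param config A [pipeline_config()].
#' @return An object of class `derived_series` with elements `abp10s`,
#'   `icp10s`, `cpp10s`, `amp10s`, `abp1m`, `icp1m`, `hr1m`.
#' @export
derive_channels <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "patient_record"))
  vf <- config$min_valid_fraction_per_window
  abp <- replace_outliers(record$abp, config$mad_multiplier)
  icp <- replace_outliers(record$icp, config$mad_multiplier)
  hr  <- replace_outliers(record$hr,  config$mad_multiplier)

  dt <- abp$sample_interval
  if (dt <= 0.25) {                       # waveform-rate input
    abp10s <- window_average(abp, 10, vf)
    icp10s <- window_average(icp, 10, vf)
    hr10s  <- window_average(hr, 10, vf)
    amp10s <- pulse_amplitude(icp, 10, vf)
  } else if (abs(dt - 10) < 1e-6) {       # pre-averaged 10-s input
    abp10s <- abp
    icp10s <- icp
    hr10s  <- hr
    if (!is.null(record$amp)) {
      if (abs(record$amp$sample_interval - 10) > 1e-6 ||
          length(record$amp$values) != length(abp$values))
        stop(sprintf("patient %s: amp channel must share the 10-s grid",
                     record$patient_id), call. = FALSE)
      amp10s <- record$amp
      if (any(amp10s$values < 0, na.rm = TRUE))
        stop("amp channel must be non-negative", call. = FALSE)
    } else {
      log_warn(sprintf(
        "patient %s: 10-s input without an amp channel; AMP (and PAx/RAC/RAP) will be missing",
        record$patient_id))
      amp10s <- signal_trace(rep(NA_real_, length(abp$values)), 10,
                             abp$start_time, "amp")
    }
  } else {
    stop(sprintf(
      "patient %s: unsupported sampling interval %gs (need waveform >= 4 Hz or 10-s means)",
      record$patient_id, dt), call. = FALSE)
  }

  cpp10s <- abp10s
  cpp10s$values <- abp10s$values - icp10s$values
  cpp10s$channel <- "cpp"

  structure(
    list(abp10s = abp10s, icp10s = icp10s, cpp10s = cpp10s, amp10s = amp10s,
         abp1m = window_average(abp10s, 60, vf),
         icp1m = window_average(icp10s, 60, vf),
         hr1m  = window_average(hr10s, 60, vf)),
    class = "derived_series"
  )
}
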