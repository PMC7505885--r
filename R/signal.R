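#' Uniformly sampled monitoring signal
#'
#' The elementary container for one monitoring channel: a numeric vector on a
#' uniform time grid. The time of sample \eqn{i} (1-based) is
#' `start_time + (i - 1) * sample_interval`, in seconds from the start of
#' monitoring. Gaps are `NA` values on the grid, never skipped rows, so the
#' grid is always contiguous.
#'
#' @param values Numeric vector (length >= 1). `NA` marks missing samples;
#'   every non-missing value must be finite.
#' @param sample_interval Sampling interval in seconds (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param channel Channel label, e.g. `"abp"`, `"icp"`, `"hr"`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, sample_interval, start_time = 0,
                         channel = "signal") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a numeric vector of length >= 1", call. = FALSE)
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0)
    stop("'sample_interval' must be a single positive number", call. = FALSE)
  if (any(is.infinite(values)))
    stop("non-missing signal values must be finite", call. = FALSE)
  structure(
    list(channel = as.character(channel)[1L],
         start_time = as.numeric(start_time)[1L],
         sample_interval = as.numeric(sample_interval),
         values = as.numeric(values)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s': %d samples @ %gs, %.2f h, %d missing>\n",
              x$channel, length(x$values), x$sample_interval,
              trace_duration_hours(x), sum(is.na(x$values))))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) * trace$sample_interval
}

#' Trace duration in hours
#'
#' Duration of the covered grid (`n * sample_interval`), counting missing
#' samples: a gap occupies time.
#'
#' @param trace A [signal_trace()].
#' @return Duration in hours.
#' @export
trace_duration_hours <- function(trace) {
  length(trace$values) * trace$sample_interval / 3600
}

# Values with sample time in [t0, t1), seconds. Returns a plain numeric vector.
trace_window_values <- function(trace, t0, t1) {
  tt <- trace_times(trace)
  trace$values[tt >= t0 & tt < t1]
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$sample_interval - b$sample_interval) <= tol * a$sample_interval &&
    abs(a$start_time - b$start_time) <= 1e-6 &&
    length(a$values) == length(b$values)
}

#' One patient's monitoring record
#'
#' Bundles the raw monitoring traces with the admission risk score and the
#' six-month outcome. ABP and ICP must share a common time origin
#' (monitoring start = 0) and sampling grid; `hr` must share the grid too.
#'
#' @param patient_id Character identifier.
#' @param abp,icp Arterial blood pressure / intracranial pressure traces
#'   (mmHg), as [signal_trace()].
#' @param hr Heart rate trace (bpm).
#' @param crash_risk CRASH model probability of unfavourable six-month
#'   outcome, in `[0, 1]`.
#' @param gos Five-point Glasgow Outcome Scale, integer in 1..5.
#' @param abp_zero_level Either `"heart"` or `"brain"`: the transducer zeroing
#'   level used for ABP. Carried as metadata; no correction is applied.
#' @param amp Optional pre-averaged 10-s ICP pulse-amplitude trace (mmHg).
#'   Required for the amplitude-based indices when the raw traces are already
#'   at 10-s resolution (cardiac pulsation can then no longer be resolved).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, abp, icp, hr, crash_risk, gos,
                           abp_zero_level = c("heart", "brain"), amp = NULL) {
  abp_zero_level <- match.arg(abp_zero_level)
  for (tr in list(abp, icp, hr))
    if (!inherits(tr, "signal_trace"))
      stop("abp, icp and hr must be signal_trace objects", call. = FALSE)
  if (!is.numeric(gos) || length(gos) != 1L || is.na(gos) ||
      gos != round(gos) || gos < 1 || gos > 5)
    stop(sprintf("patient %s: gos must be an integer in 1..5", patient_id),
         call. = FALSE)
  if (!is.numeric(crash_risk) || length(crash_risk) != 1L ||
      is.na(crash_risk) || crash_risk < 0 || crash_risk > 1)
    stop(sprintf("patient %s: crash_risk must lie in [0, 1]", patient_id),
         call. = FALSE)
  if (!same_grid(abp, icp) || !same_grid(abp, hr))
    stop(sprintf("patient %s: abp, icp and hr must share one time grid",
                 patient_id), call. = FALSE)
  if (!is.null(amp) && !inherits(amp, "signal_trace"))
    stop("'amp' must be NULL or a signal_trace", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id)[1L],
         abp = abp, icp = icp, hr = hr, amp = amp,
         crash_risk = as.numeric(crash_risk),
         gos = as.integer(gos),
         abp_zero_level = abp_zero_level),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record %s: %.1f h @ %gs, CRASH %.3f, GOS %d, ABP zero %s%s>\n",
    x$patient_id, trace_duration_hours(x$abp), x$abp$sample_interval,
    x$crash_risk, x$gos, x$abp_zero_level,
    if (is.null(x$amp)) "" else ", AMP supplied"))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis. Defaults are the values
#' used throughout: cumulative periods ending at 6/12/18/24 h, the 6-MAD
#' outlier rule, 30-sample correlation windows updated every 60 s, impairment
#' thresholds PRx > 0.35, PAx > 0.25, RAC > -0.05 and ICP > 2 mmHg, at most 6
#' model parameters, the 50% / 3-h segment inclusion rules, and a 50% validity
#' floor for window statistics.
#'
#' @param segment_ends_hours Strictly increasing ends (h) of the cumulative
#'   analysis periods, each starting at monitoring start.
#' @param mad_multiplier Scaled-MAD multiplier for outlier replacement.
#' @param prx_window_samples Number of 10-s means per correlation window.
#' @param correlation_step_seconds Update interval of the indices (s).
#' @param thresholds Named impairment thresholds for `prx`, `pax`, `rac`
#'   (index units) and `icp` (mmHg). The 2 mmHg ICP default is deliberate;
#'   20 mmHg is the conventional clinical value and can be set here.
#' @param max_total_parameters Largest model size evaluated (risk score
#'   included in the count).
#' @param min_data_fraction A period is excluded when its non-missing data
#'   cover less than this fraction of its length.
#' @param min_additional_hours A period is excluded when it adds less than
#'   this many hours of data beyond the previous period.
#' @param min_valid_fraction_per_window Minimum fraction of valid samples for
#'   a window mean, pulse amplitude or correlation to be emitted.
#' @param calibration_bins Number of equal-width calibration bins.
#' @param impairment_mode `"dose"` (mean exceedance above the threshold, in
#'   signal units) or `"fraction"` (fraction of samples above it).
#' @param ffs_criterion Forward-selection criterion: in-sample `"auc"` of the
#'   refitted model, or `"deviance"`.
#' @param ci_method AUC confidence interval: `"delong"` or `"bootstrap"`.
#' @param rng_seed Seed used by callers that randomize (the modelling itself
#'   is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(segment_ends_hours = c(6, 12, 18, 24),
                            mad_multiplier = 6,
                            prx_window_samples = 30,
                            correlation_step_seconds = 60,
                            thresholds = c(prx = 0.35, pax = 0.25,
                                           rac = -0.05, icp = 2),
                            max_total_parameters = 6,
                            min_data_fraction = 0.5,
                            min_additional_hours = 3,
                            min_valid_fraction_per_window = 0.5,
                            calibration_bins = 5,
                            impairment_mode = c("dose", "fraction"),
                            ffs_criterion = c("auc", "deviance"),
                            ci_method = c("delong", "bootstrap"),
                            rng_seed = 1L) {
  impairment_mode <- match.arg(impairment_mode)
  ffs_criterion <- match.arg(ffs_criterion)
  ci_method <- match.arg(ci_method)
  if (any(diff(segment_ends_hours) <= 0) || any(segment_ends_hours <= 0))
    stop("segment_ends_hours must be positive and strictly increasing",
         call. = FALSE)
  stopifnot(mad_multiplier > 0, prx_window_samples >= 3,
            correlation_step_seconds > 0, max_total_parameters >= 1,
            min_data_fraction > 0, min_data_fraction <= 1,
            min_additional_hours >= 0,
            min_valid_fraction_per_window > 0,
            min_valid_fraction_per_window <= 1,
            calibration_bins >= 2)
  need <- c("prx", "pax", "rac", "icp")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must name prx, pax, rac and icp", call. = FALSE)
  structure(
    list(segment_ends_hours = as.numeric(segment_ends_hours),
         mad_multiplier = mad_multiplier,
         prx_window_samples = as.integer(prx_window_samples),
         correlation_step_seconds = correlation_step_seconds,
         thresholds = thresholds[need],
         max_total_parameters = as.integer(max_total_parameters),
         min_data_fraction = min_data_fraction,
         min_additional_hours = min_additional_hours,
         min_valid_fraction_per_window = min_valid_fraction_per_window,
         calibration_bins = as.integer(calibration_bins),
         impairment_mode = impairment_mode,
         ffs_criterion = ffs_criterion,
         ci_method = ci_method,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' The 15 model parameters
#'
#' Names of the per-patient, per-period parameters, in their conventional
#' order: the admission risk score; mean ICP, ABP and HR; mean PRx, PAx, RAP
#' and RAC; the hourly slopes of PRx, PAx and RAC; and the impairment doses of
#' PRx, PAx, RAC and ICP above their thresholds.
#'
#' @return Character vector of length 15.
#' @export
parameter_names <- function() {
  c("crash_risk",
    "mean_icp", "mean_abp", "mean_hr",
    "mean_prx", "mean_pax", "mean_rap", "mean_rac",
    "slope_prx", "slope_pax", "slope_rac",
    "impair_prx", "impair_pax", "impair_rac", "impair_icp")
}

# --- logging -----------------------------------------------------------------

# Leveled logging to stderr; every patient-segment exclusion goes through
# log_warn so an audit trail of the inclusion rules is always emitted.
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}
log_info <- function(...) log_msg("info", ...)
log_warn <- function(...) log_msg("warning", ...)
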