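#' Dichotomize the Glasgow Outcome Scale
#'
#' GOS 1-3 (death, vegetative state, severe disability) is unfavourable —
#' the positive class throughout the pipeline; GOS 4-5 (moderate disability,
#' good recovery) is favourable.
#'
#' @param gos Integer vector with values in 1..5.
#' @return Factor with levels `favourable`, `unfavourable`.
#' @export
dichotomize_gos <- function(gos) {
  if (any(is.na(gos)) || any(gos != round(gos)) ||
      any(gos < 1) || any(gos > 5))
    stop("gos values must be integers in 1..5", call. = FALSE)
  factor(ifelse(gos <= 3, "unfavourable", "favourable"),
         levels = c("favourable", "unfavourable"))
}

#' Segment inclusion rules
#'
#' A cumulative period `[0, segment_end)` is excluded when (a) the data
#' present cover less than `min_data_fraction` of the period length, or (b)
#' the data added beyond the previous period amount to less than
#' `min_additional_hours`. Periods, not patients, are excluded. "Data
#' present" counts hours with non-missing paired ABP and ICP, the channels
#' feeding every cerebral parameter.
#'
#' @param data_hours Hours of data present within `[0, segment_end)`.
#' @param additional_hours Hours of data present within
#'   `[previous_end, segment_end)`.
#' @param segment_end Period end in hours.
#' @param previous_end End of the previous configured period (0 for the
#'   first).
#' @param config A [pipeline_config()].
#' @return List with `included` (logical) and `reason` (`NA` or the rule
#'   that fired).
#' @export
segment_inclusion <- function(data_hours, additional_hours, segment_end,
                              previous_end = 0,
                              config = pipeline_config()) {
  stopifnot(previous_end < segment_end, data_hours >= 0,
            additional_hours >= 0)
  if (data_hours < config$min_data_fraction * segment_end)
    return(list(included = FALSE,
                reason = sprintf("data %.2f h < %.0f%% of %g h period",
                                 data_hours, 100 * config$min_data_fraction,
                                 segment_end)))
  if (previous_end > 0 && additional_hours < config$min_additional_hours)
    return(list(included = FALSE,
                reason = sprintf(
                  "only %.2f h of data beyond the %g h period (< %g h)",
                  additional_hours, previous_end,
                  config$min_additional_hours)))
  list(included = TRUE, reason = NA_character_)
}

#' Least-squares slope of a trace over time
#'
#' Ordinary least-squares slope of value against time in hours, over the
#' non-missing samples. Used for the PRx/PAx/RAC trend parameters.
#'
#' @param trace A [signal_trace()] (or numeric values with `times_hours`).
#' @param times_hours Optional explicit sample times in hours.
#' @return Slope in signal units per hour, or `NA` if fewer than 2 valid
#'   samples or no time spread.
#' @export
linear_slope <- function(trace, times_hours = NULL) {
  if (inherits(trace, "signal_trace")) {
    y <- trace$values
    t <- trace_times(trace) / 3600
  } else {
    y <- as.numeric(trace)
    t <- times_hours
    if (is.null(t)) stop("times_hours required for plain vectors",
                         call. = FALSE)
  }
  ok <- !is.na(y) & !is.na(t)
  if (sum(ok) < 2L) return(NA_real_)
  t <- t[ok]
  y <- y[ok]
  tc <- t - mean(t)
  stt <- sum(tc * tc)
  if (stt <= 0) return(NA_real_)
  sum(tc * (y - mean(y))) / stt
}

#' Impairment dose above a threshold
#'
#' The area of a signal above a threshold divided by the total number of
#' (non-missing) samples: the mean exceedance
#' `mean(pmax(0, x - threshold))`, in signal units. With
#' `mode = "fraction"` it is instead the fraction of samples above the
#' threshold.
#'
#' @param values Numeric vector (a segment of an index or ICP series).
#' @param threshold Threshold in signal units.
#' @param mode `"dose"` (default) or `"fraction"`.
#' @return Non-negative scalar, or `NA` if all values are missing.
#' @export
impairment_dose <- function(values, threshold, mode = c("dose", "fraction")) {
  mode <- match.arg(mode)
  x <- values[!is.na(values)]
  if (length(x) == 0L) return(NA_real_)
  if (mode == "dose") mean(pmax(0, x - threshold))
  else mean(x > threshold)
}

#' The 15 parameters for one patient and period
#'
#' Applies the inclusion rules to the cumulative period `[0, segment_end)`
#' and, when included, computes the 15 parameters: means of the 1-per-minute
#' ICP, ABP and HR channels and of the four indices; OLS slopes (per hour) of
#' PRx, PAx and RAC; impairment doses of PRx, PAx, RAC and ICP above the
#' configured thresholds; and the patient's CRASH risk. All statistics are
#' missing-aware. If any of the 15 values cannot be computed the row is
#' marked not included with reason `"incomplete features"`.
#'
#' @param derived A `derived_series` from [derive_channels()].
#' @param idx An `index_series` from [compute_indices()].
#' @param record The [patient_record()].
#' @param segment_end Period end in hours.
#' @param previous_end End of the previous configured period in hours.
#' @param config A [pipeline_config()].
#' @return An object of class `segment_features`: list with `patient_id`,
#'   `segment_end_hours`, `included`, `exclusion_reason`, `gos`, `outcome`
#'   and `values` (named numeric of length 15 when included).
#' @export
extract_features <- function(derived, idx, record, segment_end,
                             previous_end = 0,
                             config = pipeline_config()) {
  stopifnot(inherits(derived, "derived_series"),
            inherits(idx, "index_series"),
            inherits(record, "patient_record"))
  t1 <- segment_end * 3600
  seg <- function(trace, t0 = 0) trace_window_values(trace, t0, t1)

  abp_m <- seg(derived$abp1m)
  icp_m <- seg(derived$icp1m)
  present <- !is.na(abp_m) & !is.na(icp_m)
  data_hours <- sum(present) / 60
  t_prev <- previous_end * 3600
  abp_add <- seg(derived$abp1m, t_prev)
  icp_add <- seg(derived$icp1m, t_prev)
  additional_hours <- sum(!is.na(abp_add) & !is.na(icp_add)) / 60

  res <- list(patient_id = record$patient_id,
              segment_end_hours = segment_end,
              gos = record$gos,
              outcome = as.character(dichotomize_gos(record$gos)),
              included = FALSE, exclusion_reason = NA_character_,
              values = NULL)

  incl <- segment_inclusion(data_hours, additional_hours, segment_end,
                            previous_end, config)
  if (!incl$included) {
    res$exclusion_reason <- incl$reason
    log_warn(sprintf("patient %s, 0-%g h period excluded: %s",
                     record$patient_id, segment_end, incl$reason))
    return(structure(res, class = "segment_features"))
  }

  prx <- seg(idx$prx); pax <- seg(idx$pax)
  rac <- seg(idx$rac); rap <- seg(idx$rap)
  prx_t <- trace_times(idx$prx) / 3600
  prx_t <- prx_t[prx_t < segment_end][seq_along(prx)]

  th <- config$thresholds
  mode <- config$impairment_mode
  vals <- c(
    crash_risk = record$crash_risk,
    mean_icp = mean(icp_m, na.rm = TRUE),
    mean_abp = mean(abp_m, na.rm = TRUE),
    mean_hr  = mean(seg(derived$hr1m), na.rm = TRUE),
    mean_prx = mean(prx, na.rm = TRUE),
    mean_pax = mean(pax, na.rm = TRUE),
    mean_rap = mean(rap, na.rm = TRUE),
    mean_rac = mean(rac, na.rm = TRUE),
    slope_prx = linear_slope(prx, prx_t),
    slope_pax = linear_slope(pax, prx_t),
    slope_rac = linear_slope(rac, prx_t),
    impair_prx = impairment_dose(prx, th[["prx"]], mode),
    impair_pax = impairment_dose(pax, th[["pax"]], mode),
    impair_rac = impairment_dose(rac, th[["rac"]], mode),
    impair_icp = impairment_dose(icp_m, th[["icp"]], mode)
  )
  vals[is.nan(vals)] <- NA_real_
  if (any(is.na(vals))) {
    res$exclusion_reason <- "incomplete features"
    log_warn(sprintf(
      "patient %s, 0-%g h period excluded: incomplete features (%s)",
      record$patient_id, segment_end,
      paste(names(vals)[is.na(vals)], collapse = ", ")))
    return(structure(res, class = "segment_features"))
  }
  res$included <- TRUE
  res$values <- vals[parameter_names()]
  structure(res, class = "segment_features")
}

#' Cohort feature matrix for one period
#'
#' Runs [extract_features()] for every patient and assembles one row per
#' patient with the 15 parameter columns plus identifiers, inclusion status,
#' raw GOS and dichotomized outcome.
#'
#' @param cohort List of [patient_record()] objects.
#' @param derived_list,idx_list Parallel lists of derived channels and index
#'   series (from [derive_channels()] / [compute_indices()]).
#' @param segment_end,previous_end Period bounds in hours.
#' @param config A [pipeline_config()].
#' @return A `data.frame` (class `feature_matrix`) with columns
#'   `patient_id`, `segment_end_hours`, `included`, `exclusion_reason`,
#'   `gos`, `outcome` and the 15 parameters.
#' @export
build_feature_matrix <- function(cohort, derived_list, idx_list, segment_end,
                                 previous_end = 0,
                                 config = pipeline_config()) {
  stopifnot(length(cohort) == length(derived_list),
            length(cohort) == length(idx_list))
  rows <- lapply(seq_along(cohort), function(i) {
    sf <- extract_features(derived_list[[i]], idx_list[[i]], cohort[[i]],
                           segment_end, previous_end, config)
    vals <- if (sf$included) as.list(sf$values) else
      stats::setNames(as.list(rep(NA_real_, 15L)), parameter_names())
    c(list(patient_id = sf$patient_id,
           segment_end_hours = sf$segment_end_hours,
           included = sf$included,
           exclusion_reason = sf$exclusion_reason,
           gos = sf$gos, outcome = sf$outcome),
      vals)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(df) <- c("feature_matrix", "data.frame")
  df
}
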