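#' Moving windowed Pearson correlation
#'
#' Correlates two aligned traces over a trailing window of `window_samples`
#' paired samples, updated every `step_seconds`. Output sample \eqn{j}
#' (0-based, timestamped on the step grid shared with the 1-per-minute
#' channels) is the Pearson correlation of the window of samples ending at
#' time `start_time + (j + 1) * step_seconds`; steps whose window would begin
#' before the trace start are missing (warm-up). Only pairs with both values
#' present enter a window; the output is missing when fewer than
#' `min_valid_fraction * window_samples` pairs remain or when either channel
#' has zero variance within the window (correlation undefined).
#'
#' @param x10s,y10s [signal_trace()] objects on one common grid (typically
#'   10-s means).
#' @param window_samples Samples per window (>= 3; default 30).
#' @param step_seconds Update interval (default 60); must be an integer
#'   multiple of the sampling interval.
#' @param min_valid_fraction Validity floor per window (default 0.5).
#' @return A `signal_trace` at `step_seconds` with values in `[-1, 1]` or
#'   `NA`.
#' @export
moving_correlation <- function(x10s, y10s, window_samples = 30,
                               step_seconds = 60, min_valid_fraction = 0.5) {
  stopifnot(inherits(x10s, "signal_trace"), inherits(y10s, "signal_trace"),
            window_samples >= 3)
  if (!same_grid(x10s, y10s))
    stop("moving_correlation inputs must share one time grid", call. = FALSE)
  dt <- x10s$sample_interval
  sps <- step_seconds / dt
  if (abs(sps - round(sps)) > 1e-8 || sps < 1)
    stop("step_seconds must be a positive integer multiple of the sampling interval",
         call. = FALSE)
  sps <- as.integer(round(sps))
  n <- length(x10s$values)
  n_out <- n %/% sps
  min_pairs <- max(3, ceiling(min_valid_fraction * window_samples))
  xv <- x10s$values
  yv <- y10s$values
  out <- rep(NA_real_, max(n_out, 0L))
  for (j in seq_len(n_out)) {
    end <- j * sps
    beg <- end - window_samples + 1L
    if (beg < 1L) next
    idx <- beg:end
    ok <- !is.na(xv[idx]) & !is.na(yv[idx])
    if (sum(ok) < min_pairs) next
    out[j] <- pearson_cor(xv[idx][ok], yv[idx][ok])
  }
  if (n_out < 1L) out <- NA_real_
  signal_trace(out, step_seconds, start_time = x10s$start_time,
               channel = paste0("r_", x10s$channel, "_", y10s$channel))
}

# Two-pass (centred) Pearson correlation; NA for zero variance.
pearson_cor <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc * xc)
  syy <- sum(yc * yc)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sum(xc * yc) / sqrt(sxx * syy)
}

#' Cerebrovascular reactivity and compensatory-reserve indices
#'
#' Computes the four moving-correlation indices at one value per minute from
#' the 10-s channel set:
#' \describe{
#'   \item{PRx}{correlation of ABP and ICP 10-s means. Positive when
#'     cerebrovascular reactivity is impaired (passive pressure transmission);
#'     negative or near zero when intact.}
#'   \item{PAx}{correlation of ABP and the ICP pulse amplitude (AMP).}
#'   \item{RAC}{correlation of AMP and CPP.}
#'   \item{RAP}{correlation of AMP and ICP.}
#' }
#' All use the same trailing window (default 30 samples, i.e. 5 min) updated
#' every minute, sharing the 1-per-minute grid of the derived channels. If
#' AMP is entirely missing, PAx/RAC/RAP are all-missing (with a warning) and
#' PRx is still computed.
#'
#' @param derived A `derived_series` from [derive_channels()].
#' @param config A [pipeline_config()].
#' @return An object of class `index_series` with elements `prx`, `pax`,
#'   `rac`, `rap`.
#' @export
compute_indices <- function(derived, config = pipeline_config()) {
  stopifnot(inherits(derived, "derived_series"))
  w <- config$prx_window_samples
  st <- config$correlation_step_seconds
  vf <- config$min_valid_fraction_per_window
  prx <- moving_correlation(derived$abp10s, derived$icp10s, w, st, vf)
  prx$channel <- "prx"
  if (all(is.na(derived$amp10s$values))) {
    log_warn("AMP entirely missing; PAx, RAC and RAP cannot be computed")
    empty <- prx
    empty$values <- rep(NA_real_, length(prx$values))
    pax <- rac <- rap <- empty
  } else {
    pax <- moving_correlation(derived$abp10s, derived$amp10s, w, st, vf)
    rac <- moving_correlation(derived$amp10s, derived$cpp10s, w, st, vf)
    rap <- moving_correlation(derived$amp10s, derived$icp10s, w, st, vf)
  }
  pax$channel <- "pax"
  rac$channel <- "rac"
  rap$channel <- "rap"
  structure(list(prx = prx, pax = pax, rac = rac, rap = rap),
            class = "index_series")
}
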