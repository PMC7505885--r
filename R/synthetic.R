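#' Synthetic cohort configuration
#'
#' Parameters of the seeded cohort generator. Defaults describe the study
#' conditions the pipeline targets: 44% prevalence of unfavourable outcome,
#' a baseline risk score discriminating at AUC 0.76, slow vasogenic
#' pressure waves in 0.005-0.04 Hz, ABP-to-ICP slow-wave coupling of +0.7
#' when cerebrovascular reactivity is impaired and -0.5 when intact (the
#' latent reactivity state is linked to outcome), ~1.1 Hz cardiac ICP
#' pulsation of 2.5 mmHg peak-to-trough, and occasional gaps and artifact
#' spikes. Outcome signal is planted only at the latent level (reactivity
#' state, ABP baseline, risk score) — never written into features directly —
#' so every parameter must be recovered through the real pipeline.
#'
#' @param n_patients Cohort size (>= 2).
#' @param duration_hours Monitoring duration per patient (default 24).
#' @param waveform_rate_hz Output sampling rate. `0` emits 10-s mean
#'   channels directly (plus a pre-averaged AMP channel); positive rates
#'   (>= 4, default 25) emit waveforms with cardiac pulsation so AMP is
#'   computed by the pipeline.
#' @param prevalence_unfavourable P(unfavourable outcome), in (0, 1).
#' @param crash_auc_target Between-class discrimination of the simulated
#'   risk score; class-conditional Beta distributions are calibrated so
#'   P(score_unfav > score_fav) equals this.
#' @param coupling_impaired,coupling_intact Mean slow-wave ABP-ICP coupling
#'   for the impaired / intact latent reactivity states, in [-1, 1].
#' @param coupling_sd Between-patient SD of the coupling draw.
#' @param reactivity_link P(impaired | unfavourable) and P(impaired |
#'   favourable); equal values remove all reactivity-outcome signal.
#' @param slow_wave_band_hz Frequency band of the vasogenic waves.
#' @param slow_wave_sd_mmHg SD of the ABP slow-wave component.
#' @param icp_slow_sd_mmHg SD of the ICP slow-wave component.
#' @param amp_slow_sd_mmHg SD of the AMP slow-wave component (10-s mode).
#' @param cardiac_rate_hz Cardiac frequency of the simulated pulsation.
#' @param icp_pulse_amp_mmHg Peak-to-trough ICP cardiac pulsation.
#' @param abp_pulse_amp_mmHg Peak-to-trough ABP pulse pressure.
#' @param abp_baseline_mmHg,icp_baseline_mmHg,hr_baseline_bpm Channel
#'   baselines.
#' @param noise_sd Named per-channel SD of 10-s-scale measurement noise
#'   (`abp`, `icp`, `hr`, `amp`).
#' @param gap_rate Expected missing-data gaps per 24 h (exponential gap
#'   lengths, mean 15 min, all channels together).
#' @param spike_rate Expected artifact spikes per 24 h (single-sample
#'   excursions on ABP or ICP, repaired downstream by the MAD rule).
#' @param effect_abp_mmHg Shift of the ABP baseline for unfavourable
#'   patients (default -8: lower pressure with worse outcome); 0 removes
#'   the signal.
#' @param gos_probs_unfav,gos_probs_fav Outcome-conditional GOS
#'   distributions over 1..3 and 4..5.
#' @param rng_seed Integer seed; generation is fully deterministic given
#'   the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 45L,
                       duration_hours = 24,
                       waveform_rate_hz = 25,
                       prevalence_unfavourable = 0.44,
                       crash_auc_target = 0.76,
                       coupling_impaired = 0.7,
                       coupling_intact = -0.5,
                       coupling_sd = 0.1,
                       reactivity_link = c(unfav = 0.8, fav = 0.2),
                       slow_wave_band_hz = c(0.005, 0.04),
                       slow_wave_sd_mmHg = 4,
                       icp_slow_sd_mmHg = 2,
                       amp_slow_sd_mmHg = 0.6,
                       cardiac_rate_hz = 1.1,
                       icp_pulse_amp_mmHg = 2.5,
                       abp_pulse_amp_mmHg = 40,
                       abp_baseline_mmHg = 85,
                       icp_baseline_mmHg = 12,
                       hr_baseline_bpm = 75,
                       noise_sd = c(abp = 1.5, icp = 1, hr = 2, amp = 0.3),
                       gap_rate = 2,
                       spike_rate = 5,
                       effect_abp_mmHg = -8,
                       gos_probs_unfav = c(`1` = 0.65, `2` = 0.05,
                                           `3` = 0.30),
                       gos_probs_fav = c(`4` = 0.4, `5` = 0.6),
                       rng_seed = 1L) {
  stopifnot(n_patients >= 2, duration_hours > 0,
            waveform_rate_hz == 0 || waveform_rate_hz >= 4,
            prevalence_unfavourable > 0, prevalence_unfavourable < 1,
            crash_auc_target > 0.5, crash_auc_target < 1,
            abs(coupling_impaired) <= 1, abs(coupling_intact) <= 1,
            all(reactivity_link >= 0), all(reactivity_link <= 1),
            gap_rate >= 0, spike_rate >= 0,
            all(noise_sd >= 0),
            abs(sum(gos_probs_unfav) - 1) < 1e-8,
            abs(sum(gos_probs_fav) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

# AUC between Beta(m1*k, (1-m1)*k) and Beta(m0*k, (1-m0)*k):
# P(X1 > X0) = int F0(x) f1(x) dx.
beta_pair_auc <- function(m1, m0, kappa) {
  f <- function(x) stats::pbeta(x, m0 * kappa, (1 - m0) * kappa) *
    stats::dbeta(x, m1 * kappa, (1 - m1) * kappa)
  stats::integrate(f, 0, 1, rel.tol = 1e-9)$value
}

# Class means for the risk-score Beta draws, placed symmetrically around
# `center` on the logit scale with the separation solved so the
# between-class AUC hits the target. Memoized: the root-find is exact and
# re-used across patients.
.crash_cache <- new.env(parent = emptyenv())
crash_beta_means <- function(target_auc, kappa = 8,
                             center = stats::qlogis(0.45)) {
  key <- sprintf("%.10f|%g|%.10f", target_auc, kappa, center)
  if (!is.null(.crash_cache[[key]])) return(.crash_cache[[key]])
  f <- function(delta) {
    beta_pair_auc(stats::plogis(center + delta / 2),
                  stats::plogis(center - delta / 2), kappa) - target_auc
  }
  delta <- stats::uniroot(f, c(1e-6, 8), tol = 1e-8)$root
  res <- c(unfav = stats::plogis(center + delta / 2),
           fav = stats::plogis(center - delta / 2))
  .crash_cache[[key]] <- res
  res
}

# Standardized sum of slow sinusoids with random frequencies and phases.
slow_wave <- function(t_sec, band) {
  k <- 6L
  freqs <- stats::runif(k, band[1], band[2])
  phases <- stats::runif(k, 0, 2 * pi)
  amps <- stats::runif(k, 0.3, 1)
  s <- rep(0, length(t_sec))
  for (i in seq_len(k)) s <- s + amps[i] * sin(2 * pi * freqs[i] * t_sec +
                                                 phases[i])
  s / stats::sd(s)
}

#' Generate one synthetic patient
#'
#' Builds the slow-wave structure on a 10-s grid: ABP is a baseline (plus
#' the outcome-conditional shift) plus a standardized slow wave and noise;
#' the ICP slow component is `c * abp_wave + sqrt(1 - c^2) * independent`,
#' so its correlation with the ABP wave equals the patient's coupling `c`
#' exactly before noise; AMP shares the coupling so the amplitude-based
#' indices carry the same latent state. In waveform mode the 10-s structure
#' is interpolated to the output rate and cardiac pulsation is added; in
#' 10-s mode an AMP channel is emitted directly. Gaps and artifact spikes
#' are injected at the configured rates. GOS and the risk score are drawn
#' from their outcome-conditional distributions.
#'
#' @param config A [sim_config()].
#' @param outcome `"unfavourable"` or `"favourable"`.
#' @param seed Integer seed for this patient.
#' @param patient_id Identifier (default derived from the seed).
#' @param coupling Optional fixed coupling, overriding the latent-state
#'   draw (used for sign-recovery experiments).
#' @return List with `record` (a [patient_record()]) and `truth` (latent
#'   state, coupling, baselines).
#' @export
generate_patient <- function(config, outcome = c("unfavourable", "favourable"),
                             seed = 1L, patient_id = NULL,
                             coupling = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(patient_id)) patient_id <- sprintf("P%06d", seed %% 1000000L)
  unfav <- outcome == "unfavourable"

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  n10 <- floor(config$duration_hours * 360)
  t10 <- (seq_len(n10) - 1) * 10

  p_imp <- if (unfav) config$reactivity_link[["unfav"]] else
    config$reactivity_link[["fav"]]
  impaired <- stats::runif(1) < p_imp
  if (is.null(coupling)) {
    mu_c <- if (impaired) config$coupling_impaired else config$coupling_intact
    coupling <- max(-0.95, min(0.95,
                               stats::rnorm(1, mu_c, config$coupling_sd)))
  }

  wave_abp <- slow_wave(t10, config$slow_wave_band_hz)
  wave_ind <- slow_wave(t10, config$slow_wave_band_hz)
  wave_amp <- slow_wave(t10, config$slow_wave_band_hz)
  icp_wave <- coupling * wave_abp + sqrt(1 - coupling^2) * wave_ind
  amp_wave <- coupling * wave_abp + sqrt(1 - coupling^2) * wave_amp

  abp_base <- config$abp_baseline_mmHg + stats::rnorm(1, 0, 4) +
    if (unfav) config$effect_abp_mmHg else 0
  icp_base <- config$icp_baseline_mmHg + stats::rnorm(1, 0, 2.5)
  hr_base <- config$hr_baseline_bpm + stats::rnorm(1, 0, 6)

  ns <- config$noise_sd
  abp10 <- abp_base + config$slow_wave_sd_mmHg * wave_abp +
    stats::rnorm(n10, 0, ns[["abp"]])
  icp10 <- icp_base + config$icp_slow_sd_mmHg * icp_wave +
    stats::rnorm(n10, 0, ns[["icp"]])
  hr_drift <- stats::filter(stats::rnorm(n10, 0, 0.4), 0.995, "recursive")
  hr10 <- pmin(140, pmax(40, hr_base + as.numeric(hr_drift) +
                           stats::rnorm(n10, 0, ns[["hr"]])))
  amp10 <- pmax(0.2, config$icp_pulse_amp_mmHg +
                  config$amp_slow_sd_mmHg * amp_wave +
                  stats::rnorm(n10, 0, ns[["amp"]]))

  # gaps (shared across channels) and artifact spikes, on the 10-s grid
  day_frac <- config$duration_hours / 24
  n_gaps <- stats::rpois(1, config$gap_rate * day_frac)
  gap_idx <- integer(0)
  if (n_gaps > 0) {
    for (g in seq_len(n_gaps)) {
      len <- max(1L, ceiling(stats::rexp(1, rate = 1 / 90)))  # ~15 min mean
      beg <- sample.int(n10, 1)
      gap_idx <- c(gap_idx, beg:min(n10, beg + len - 1L))
    }
    gap_idx <- unique(gap_idx)
  }
  n_spikes <- stats::rpois(1, config$spike_rate * day_frac)
  spike_idx <- if (n_spikes > 0) sample.int(n10, min(n_spikes, n10)) else
    integer(0)
  spike_chan <- sample(c("abp", "icp"), length(spike_idx), replace = TRUE)

  rate <- config$waveform_rate_hz
  if (rate == 0) {
    # single-sample artifact excursions, far beyond 6 scaled MADs
    abp10[spike_idx[spike_chan == "abp"]] <-
      abp10[spike_idx[spike_chan == "abp"]] +
      stats::runif(sum(spike_chan == "abp"), 60, 120)
    icp10[spike_idx[spike_chan == "icp"]] <-
      icp10[spike_idx[spike_chan == "icp"]] +
      stats::runif(sum(spike_chan == "icp"), 40, 80)
  }
  if (rate > 0) {
    dt <- 1 / rate
    tw <- seq(0, n10 * 10 - dt, by = dt)
    # spline (not linear) upsampling: kink-free intra-window paths, so the
    # pulse-amplitude stage reads cardiac pulsation, not interpolation
    # corners of the slow structure
    up <- function(x) stats::spline(t10 + 5, x, xout = tw,
                                    method = "fmm")$y
    ph <- stats::runif(2, 0, 2 * pi)
    abp_w <- up(abp10) + config$abp_pulse_amp_mmHg / 2 *
      sin(2 * pi * config$cardiac_rate_hz * tw + ph[1])
    icp_w <- up(icp10) + up(amp10) / 2 *
      sin(2 * pi * config$cardiac_rate_hz * tw + ph[2])
    hr_w <- up(hr10)
    # burst artifacts (~2.5 s) sized to exceed 6 scaled MADs of the pulsatile
    # waveform, so the repair stage is exercised at waveform rate too
    if (length(spike_idx) > 0) {
      for (s in seq_along(spike_idx)) {
        w0 <- round((spike_idx[s] - 1) * 10 * rate) + 1L
        wi <- w0:min(length(tw), w0 + ceiling(2.5 * rate))
        if (spike_chan[s] == "abp")
          abp_w[wi] <- abp_w[wi] + stats::runif(1, 150, 250)
        else icp_w[wi] <- icp_w[wi] + stats::runif(1, 60, 100)
      }
    }
    if (length(gap_idx) > 0) {
      gw <- which((floor(tw / 10) + 1L) %in% gap_idx)
      abp_w[gw] <- icp_w[gw] <- hr_w[gw] <- NA_real_
    }
    record <- patient_record(
      patient_id,
      abp = signal_trace(abp_w, dt, 0, "abp"),
      icp = signal_trace(icp_w, dt, 0, "icp"),
      hr = signal_trace(hr_w, dt, 0, "hr"),
      crash_risk = draw_crash(config, unfav),
      gos = draw_gos(config, unfav),
      abp_zero_level = sample(c("heart", "brain"), 1, prob = c(0.75, 0.25)))
  } else {
    if (length(gap_idx) > 0)
      abp10[gap_idx] <- icp10[gap_idx] <- hr10[gap_idx] <-
        amp10[gap_idx] <- NA_real_
    record <- patient_record(
      patient_id,
      abp = signal_trace(abp10, 10, 0, "abp"),
      icp = signal_trace(icp10, 10, 0, "icp"),
      hr = signal_trace(hr10, 10, 0, "hr"),
      crash_risk = draw_crash(config, unfav),
      gos = draw_gos(config, unfav),
      abp_zero_level = sample(c("heart", "brain"), 1, prob = c(0.75, 0.25)),
      amp = signal_trace(amp10, 10, 0, "amp"))
  }
  list(record = record,
       truth = list(patient_id = patient_id, outcome = outcome,
                    impaired = impaired, coupling = coupling,
                    abp_baseline = abp_base, seed = seed))
}

draw_gos <- function(config, unfav) {
  if (unfav) sample(1:3, 1, prob = config$gos_probs_unfav)
  else sample(4:5, 1, prob = config$gos_probs_fav)
}

draw_crash <- function(config, unfav) {
  mm <- crash_beta_means(config$crash_auc_target)
  m <- if (unfav) mm[["unfav"]] else mm[["fav"]]
  kappa <- 8
  stats::rbeta(1, m * kappa, (1 - m) * kappa)
}

#' Generate a synthetic cohort
#'
#' Draws outcomes at the configured prevalence (forcing at least one
#' patient per class), then generates each patient with a seed derived
#' deterministically from `rng_seed`. The returned truth table records the
#' latent reactivity state, coupling and baselines for recovery tests.
#'
#' @param config A [sim_config()].
#' @return List with `records` (list of [patient_record()]) and `truth`
#'   (data.frame, one row per patient).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_patients >= 2)
  n <- as.integer(config$n_patients)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(config$rng_seed)
  unfav <- stats::runif(n) < config$prevalence_unfavourable
  if (all(unfav)) unfav[n] <- FALSE
  if (!any(unfav)) unfav[n] <- TRUE
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(seq_len(n), function(i)
    generate_patient(config,
                     if (unfav[i]) "unfavourable" else "favourable",
                     seed = seeds[i],
                     patient_id = sprintf("P%03d", i)))
  truth <- do.call(rbind, lapply(out, function(o)
    as.data.frame(o$truth, stringsAsFactors = FALSE)))
  list(records = lapply(out, `[[`, "record"), truth = truth)
}
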