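# Shared fixtures, all generated in code.

# constant-channel patient at 10-s resolution: every feature has a
# hand-computable value. A nonzero jitter adds one shared in-phase sine to
# all channels (scaled per channel) so every pairwise window correlation is
# exactly +1 while channel means stay at the stated constants.
constant_patient <- function(hours = 6, abp = 80, icp = 10, hr = 70,
                             amp = 1.5, jitter = 0) {
  n <- hours * 360
  s <- sin(seq_len(n))
  mk <- function(v, scale, ch)
    signal_trace(rep(v, n) + jitter * scale * s, 10, 0, ch)
  patient_record("const", abp = mk(abp, 1, "abp"), icp = mk(icp, 0.6, "icp"),
                 hr = mk(hr, 1, "hr"), crash_risk = 0.42, gos = 4,
                 amp = mk(amp, 0.4, "amp"))
}

# tiny 10-s-mode simulation config for fast tests
quick_sim <- function(n = 20, hours = 6, seed = 1L, ...) {
  sim_config(n_patients = n, duration_hours = hours, waveform_rate_hz = 0,
             rng_seed = seed, ...)
}

# feature matrix with a planted perfectly-informative column, for the
# selection machinery
toy_matrix <- function(n = 60, seed = 5) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- cbind(crash_risk = stats::plogis(0.8 * y + rnorm(n)),
             noise1 = rnorm(n),
             noise2 = rnorm(n),
             signal = y * 2 - 1 + rnorm(n, 0, 0.1))
  list(x = x, y = y)
}

expect_trace_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$sample_interval, b$sample_interval, tolerance = tol)
  expect_equal(a$start_time, b$start_time, tolerance = tol)
  expect_equal(a$values, b$values, tolerance = tol)
}
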