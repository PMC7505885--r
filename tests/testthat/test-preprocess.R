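test_that("clean traces are fixed points of outlier replacement", {
  tr <- signal_trace(c(5, 5, 5, 5), 1)
  expect_equal(replace_outliers(tr)$values, c(5, 5, 5, 5))
  ramp <- signal_trace(1:100, 1)
  expect_equal(replace_outliers(ramp)$values, as.numeric(1:100))
})

test_that("a spike against zero MAD is flagged and interpolated", {
  tr <- signal_trace(c(1, 1, 1, 100, 1, 1), 1)
  expect_equal(replace_outliers(tr)$values, rep(1, 6))
  # spike at the edge takes the nearest unflagged value
  tr2 <- signal_trace(c(100, 1, 1, 1, 1, 1), 1)
  expect_equal(replace_outliers(tr2)$values, rep(1, 6))
})

test_that("outlier replacement skips missing samples and is idempotent", {
  set.seed(31)
  x <- rnorm(500, 80, 2)
  x[c(50, 200, 350)] <- c(200, -40, 180)
  x[100:120] <- NA
  tr <- signal_trace(x, 10)
  once <- replace_outliers(tr)
  expect_true(all(is.na(once$values[100:120])))
  expect_lt(max(once$values, na.rm = TRUE), 100)
  twice <- replace_outliers(once)
  expect_identical(twice$values, once$values)
})

test_that("replace_outliers rejects degenerate traces", {
  expect_error(replace_outliers(signal_trace(c(1, NA, 2), 1)),
               "non-missing")
})

test_that("window averages reproduce hand-computed means", {
  expect_equal(window_average(signal_trace(rep(7, 50), 1), 10)$values,
               rep(7, 5))
  expect_equal(window_average(signal_trace(1:10, 1), 10)$values, 5.5)
  x <- c(1:10, rep(NA, 10), 21:30)
  out <- window_average(signal_trace(x, 1), 10)
  expect_equal(out$values, c(5.5, NA, 25.5))
  expect_equal(out$sample_interval, 10)
})

test_that("window averaging is affine-equivariant and length floor(n/k)", {
  set.seed(7)
  x <- rnorm(95)
  tr <- signal_trace(x, 1)
  base <- window_average(tr, 10)$values
  expect_length(base, 9)
  shifted <- window_average(signal_trace(3 * x + 2, 1), 10)$values
  expect_equal(shifted, 3 * base + 2)
})

test_that("window validity floor controls missing output", {
  x <- c(1:4, rep(NA, 6))                 # 40% valid in one 10-s window
  expect_true(is.na(window_average(signal_trace(x, 1), 10, 0.5)$values))
  expect_equal(window_average(signal_trace(x, 1), 10, 0.3)$values, 2.5)
  expect_error(window_average(signal_trace(1:10, 10), 5), "must be >=")
})

test_that("pulse amplitude recovers peak-to-trough of a sine", {
  t <- seq(0, 60 - 1 / 25, by = 1 / 25)
  icp <- signal_trace(10 + 1.5 * sin(2 * pi * 1 * t), 1 / 25, 0, "icp")
  amp <- pulse_amplitude(icp, 10)
  expect_equal(amp$values, rep(3, 6), tolerance = 0.02)
  # constant waveform has zero pulsation
  expect_equal(pulse_amplitude(signal_trace(rep(8, 250), 1 / 25), 10)$values,
               rep(0, 1))
})

test_that("pulse amplitude is drift- and offset-invariant", {
  t <- seq(0, 30 - 1 / 25, by = 1 / 25)
  base <- 10 + 1.5 * sin(2 * pi * 1.1 * t)
  drift <- base + 0.2 * t                 # 2 mmHg drift per 10-s window
  a0 <- pulse_amplitude(signal_trace(base, 1 / 25), 10)$values
  a1 <- pulse_amplitude(signal_trace(drift, 1 / 25), 10)$values
  a2 <- pulse_amplitude(signal_trace(base + 50, 1 / 25), 10)$values
  expect_equal(a0, rep(3, 3), tolerance = 0.02)
  expect_equal(a1, a0, tolerance = 0.03)
  expect_equal(a2, a0)
  expect_error(pulse_amplitude(signal_trace(1:100, 1), 10), ">= 4 Hz")
})

test_that("derived channels have the expected grids and algebra", {
  set.seed(11)
  t <- seq(0, 3600 - 1 / 25, by = 1 / 25)
  # slow waves chosen slow enough that their within-window curvature is
  # negligible next to the planted 2.5 mmHg pulsation
  abp <- 80 + 5 * sin(2 * pi * 0.002 * t) + 20 * sin(2 * pi * 1.1 * t)
  icp <- 10 + 2 * sin(2 * pi * 0.002 * t + 1) + 1.25 * sin(2 * pi * 1.1 * t)
  hr <- rep(70, length(t))
  rec <- patient_record("w", signal_trace(abp, 1 / 25, 0, "abp"),
                        signal_trace(icp, 1 / 25, 0, "icp"),
                        signal_trace(hr, 1 / 25, 0, "hr"),
                        crash_risk = 0.3, gos = 4)
  d <- derive_channels(rec)
  expect_length(d$abp10s$values, 360)
  expect_length(d$abp1m$values, 60)
  expect_equal(d$cpp10s$values, d$abp10s$values - d$icp10s$values)
  expect_true(all(d$amp10s$values >= 0))
  expect_equal(mean(d$amp10s$values), 2.5, tolerance = 0.05)
})

test_that("gaps propagate into derived channels and are not interpolated", {
  rec <- constant_patient(hours = 2)
  gap <- 200:260                       # a 10-min gap on the 10-s grid
  rec$abp$values[gap] <- NA
  d <- derive_channels(rec)
  expect_true(all(is.na(d$abp10s$values[gap])))
  expect_true(all(is.na(d$cpp10s$values[gap])))
  expect_true(anyNA(d$abp1m$values))
  expect_false(anyNA(d$icp1m$values))
})

test_that("10-s input without an amp channel leaves AMP missing", {
  rec <- constant_patient(hours = 1)
  rec$amp <- NULL
  expect_message(d <- derive_channels(rec), "amp")
  expect_true(all(is.na(d$amp10s$values)))
})
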