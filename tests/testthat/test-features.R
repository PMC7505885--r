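test_that("GOS dichotomization splits 1-3 vs 4-5", {
  expect_equal(as.character(dichotomize_gos(c(1, 2, 3))),
               rep("unfavourable", 3))
  expect_equal(as.character(dichotomize_gos(c(4, 5))),
               rep("favourable", 2))
  expect_error(dichotomize_gos(6), "1..5")
  expect_error(dichotomize_gos(0), "1..5")
})

test_that("segment inclusion applies the 50% and 3-h rules", {
  # 5 h of data in the 0-12 h period: below half
  r <- segment_inclusion(5, 5, 12, 6)
  expect_false(r$included)
  expect_match(r$reason, "50%")
  # data to 14.5 h in the 0-18 h period: only 2.5 h beyond 12 h
  r2 <- segment_inclusion(14.5, 2.5, 18, 12)
  expect_false(r2$included)
  expect_match(r2$reason, "beyond")
  # full data is always included
  for (seg in c(6, 12, 18, 24))
    expect_true(segment_inclusion(seg, 6, seg,
                                  max(0, seg - 6))$included)
  # the first period has no 3-h-additional constraint
  expect_true(segment_inclusion(3.5, 3.5, 6, 0)$included)
})

test_that("linear slopes match closed-form least squares", {
  expect_equal(linear_slope(c(0, 1, 2, 3), times_hours = 0:3), 1)
  expect_equal(linear_slope(rep(2, 10), times_hours = 1:10), 0)
  # closed form: sum(tc*yc)/sum(tc^2) = 0.5/5; cross-checked against lm()
  expect_equal(linear_slope(c(0.1, 0.4, 0.2, 0.5), times_hours = 0:3), 0.1)
  expect_equal(linear_slope(c(0.1, 0.4, 0.2, 0.5), times_hours = 0:3),
               unname(coef(lm(c(0.1, 0.4, 0.2, 0.5) ~ c(0:3)))[2]))
  expect_equal(linear_slope(c(NA, 1, NA, 3), times_hours = 0:3), 1)
  expect_true(is.na(linear_slope(c(1, NA, NA), times_hours = 0:2)))
  tr <- signal_trace(c(0, 1, 2, 3), 3600)
  expect_equal(linear_slope(tr), 1)
})

test_that("impairment dose is the mean exceedance above threshold", {
  expect_equal(impairment_dose(c(0.1, 0.2, 0.3), 0.35), 0)
  expect_equal(impairment_dose(rep(1.35, 5), 0.35), 1)
  expect_equal(impairment_dose(c(0.5, 0.2, 0.45), 0.35), 0.25 / 3)
  expect_equal(impairment_dose(c(0.5, NA, 0.2), 0.35), 0.15 / 2)
  expect_true(is.na(impairment_dose(c(NA, NA), 0.35)))
  expect_equal(impairment_dose(c(0.5, 0.2, 0.45), 0.35, "fraction"), 2 / 3)
})

test_that("impairment dose is monotone non-increasing in the threshold", {
  set.seed(3)
  x <- rnorm(200, 0.2, 0.3)
  th <- seq(-0.5, 1, by = 0.1)
  d <- vapply(th, function(t) impairment_dose(x, t), numeric(1))
  expect_true(all(diff(d) <= 1e-12))
  expect_equal(impairment_dose(x, max(x)), 0)
})

test_that("constant channels flow through every feature formula", {
  rec <- constant_patient(hours = 6, abp = 80, icp = 10, hr = 70)
  d <- derive_channels(rec)
  ix <- compute_indices(d)          # zero variance: all indices missing
  sf <- extract_features(d, ix, rec, 6, 0)
  expect_false(sf$included)         # index means cannot be computed
  expect_equal(sf$exclusion_reason, "incomplete features")

  # jittered channels give defined indices; check the closed-form values
  rec2 <- constant_patient(hours = 6, jitter = 0.5)
  d2 <- derive_channels(rec2)
  ix2 <- compute_indices(d2)
  sf2 <- extract_features(d2, ix2, rec2, 6, 0)
  expect_true(sf2$included)
  v <- sf2$values
  expect_equal(sort(names(v)), sort(parameter_names()))
  expect_equal(unname(v["mean_abp"]), 80, tolerance = 1e-4)
  expect_equal(unname(v["mean_icp"]), 10, tolerance = 1e-4)
  expect_equal(unname(v["mean_hr"]), 70, tolerance = 1e-4)
  expect_equal(unname(v["crash_risk"]), 0.42)
  expect_equal(unname(v["impair_icp"]), 8, tolerance = 1e-4)
  # all channels share one in-phase wave, so every index is exactly +1
  expect_equal(unname(v["mean_prx"]), 1, tolerance = 1e-10)
  expect_equal(unname(v["impair_prx"]), 1 - 0.35, tolerance = 1e-10)
  expect_equal(unname(v["impair_pax"]), 1 - 0.25, tolerance = 1e-10)
  expect_equal(unname(v["impair_rac"]), 1 + 0.05, tolerance = 1e-10)
  expect_equal(unname(v["slope_rac"]), 0, tolerance = 1e-10)
})

test_that("a constant index above threshold yields dose value minus threshold", {
  expect_equal(impairment_dose(rep(0.55, 100), 0.35), 0.2)
})

test_that("prefix consistency: 6-h features agree between short and long runs", {
  cfg <- quick_sim(hours = 12, seed = 4, gap_rate = 0, spike_rate = 0)
  rec <- generate_patient(cfg, "favourable", seed = 9)$record
  d <- derive_channels(rec)
  ix <- compute_indices(d)
  full <- extract_features(d, ix, rec, 6, 0)

  short <- rec
  keep <- 6 * 360
  for (ch in c("abp", "icp", "hr", "amp"))
    short[[ch]]$values <- short[[ch]]$values[seq_len(keep)]
  ds <- derive_channels(short)
  ixs <- compute_indices(ds)
  trunc <- extract_features(ds, ixs, short, 6, 0)
  expect_equal(trunc$values, full$values, tolerance = 1e-10)
})

test_that("feature matrix assembles one row per patient with outcomes", {
  cfg <- quick_sim(n = 8, hours = 6, seed = 2)
  co <- generate_cohort(cfg)
  derived <- lapply(co$records, derive_channels)
  idx <- lapply(derived, compute_indices)
  fm <- build_feature_matrix(co$records, derived, idx, 6, 0)
  expect_equal(nrow(fm), 8)
  expect_true(all(parameter_names() %in% names(fm)))
  expect_equal(fm$outcome,
               as.character(dichotomize_gos(fm$gos)))
  inc <- fm[fm$included, parameter_names()]
  expect_false(anyNA(inc))
})

test_that("short monitoring excludes the later periods only", {
  cfg <- quick_sim(n = 4, hours = 5, seed = 6)
  co <- generate_cohort(cfg)
  derived <- lapply(co$records, derive_channels)
  idx <- lapply(derived, compute_indices)
  fm6 <- suppressMessages(
    build_feature_matrix(co$records, derived, idx, 6, 0))
  fm12 <- suppressMessages(
    build_feature_matrix(co$records, derived, idx, 12, 6))
  expect_true(any(fm6$included))
  expect_false(any(fm12$included))
})
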