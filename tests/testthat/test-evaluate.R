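test_that("ROC endpoints, monotonicity and worked AUC values", {
  # perfect separation
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  # 3 of 4 pairs concordant
  r2 <- roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0.75)
  # all-tied scores land on the diagonal
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  pts <- r2$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both")
})

test_that("trapezoid AUC equals the tie-adjusted concordant-pair count", {
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(99)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))     # force ties
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-14)
    expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1,
                 tolerance = 1e-14)
    # invariance under strictly increasing transform
    expect_equal(roc_auc(exp(2 * s), y)$auc, roc_auc(s, y)$auc,
                 tolerance = 1e-14)
  }
})

test_that("AUC and DeLong interval agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- rbinom(60, 1, 0.45)
  y[1:2] <- c(0, 1)
  s <- plogis(y + rnorm(60))
  ours <- auc_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  ci <- suppressWarnings(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$lo, as.numeric(ci[1]), tolerance = 1e-6)
  expect_equal(ours$hi, as.numeric(ci[3]), tolerance = 1e-6)
})

test_that("degenerate AUC collapses the interval with a warning", {
  expect_warning(ci <- auc_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
                 "degenerate")
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
})

test_that("DeLong and bootstrap intervals agree on moderate samples", {
  set.seed(10)
  n <- 45
  y <- c(rep(1, 20), rep(0, 25))
  s <- plogis(0.9 * y + rnorm(n))
  dl <- auc_ci(s, y, method = "delong")
  bs <- auc_ci(s, y, method = "bootstrap", n_boot = 2000)
  expect_equal(dl$lo, bs$lo, tolerance = 0.03)
  expect_equal(dl$hi, bs$hi, tolerance = 0.03)
})

test_that("Youden cutoff reproduces the enumerated worked example", {
  s <- c(0.9, 0.4, 0.6, 0.1)
  y <- c(1, 1, 0, 0)
  yc <- youden_cutoff(s, y)
  expect_equal(yc$youden, 0.5)
  expect_equal(yc$cutoff, 0.25)     # tie with 0.75 broken downward
  expect_equal(yc$accuracy, 0.75)
  # perfect separation classifies everything
  expect_equal(youden_cutoff(c(0.9, 0.8, 0.2, 0.1),
                             c(1, 1, 0, 0))$accuracy, 1)
  # all-equal scores: J = 0 everywhere, lowest cutoff predicts everyone
  # positive, accuracy = the (here majority) positive rate
  yc2 <- youden_cutoff(rep(0.4, 10), c(rep(1, 6), rep(0, 4)))
  expect_equal(yc2$youden, 0)
  expect_equal(yc2$accuracy, 0.6)
})

test_that("calibration bins partition patients with coherent fractions", {
  # probabilities equal to labels: two perfectly calibrated bins
  y <- rep(c(0, 1), each = 10)
  cb <- calibration_bins(as.numeric(y), y, 5)
  expect_equal(nrow(cb), 2)
  expect_equal(cb$mean_predicted, cb$observed_fraction)
  expect_equal(sum(cb$n), 20)
  # single-bin case: predicted 0.5 vs observed prevalence
  cb2 <- calibration_bins(rep(0.5, 25), c(rep(1, 11), rep(0, 14)), 5)
  expect_equal(nrow(cb2), 1)
  expect_equal(cb2$mean_predicted, 0.5)
  expect_equal(cb2$observed_fraction, 11 / 25)
  # empty bins are omitted, counts still sum to n
  set.seed(2)
  p <- c(runif(10, 0, 0.1), runif(10, 0.9, 1))
  cb3 <- calibration_bins(p, rbinom(20, 1, p), 5)
  expect_equal(nrow(cb3), 2)
  expect_equal(sum(cb3$n), 20)
  expect_true(all(cb3$observed_fraction >= 0 & cb3$observed_fraction <= 1))
})

test_that("misclassification table matches a hand count by GOS level", {
  gos <- c(1, 1, 2, 3, 3, 4, 4, 5, 5, 5)
  truth <- as.numeric(gos <= 3)
  # all correct
  mc <- misclassification_by_gos(truth, gos)
  expect_equal(mc$wrong, rep(0L, 5))
  expect_equal(mc$total, c(2L, 1L, 2L, 2L, 3L))
  # flip one GOS-1 patient to predicted favourable and one GOS-5 to
  # predicted unfavourable
  pred <- truth
  pred[1] <- 0
  pred[10] <- 1
  mc2 <- misclassification_by_gos(pred, gos)
  expect_equal(mc2$wrong, c(1L, 0L, 0L, 0L, 1L))
  expect_error(misclassification_by_gos(truth, c(gos[-1], 7)), "1..5")
})

test_that("evaluate_probabilities bundles coherent components", {
  set.seed(5)
  n <- 45
  gos <- sample(1:5, n, replace = TRUE,
                prob = c(0.29, 0.02, 0.13, 0.22, 0.34))
  gos[1:2] <- c(1, 5)
  y <- dichotomize_gos(gos)
  p <- plogis(1.2 * (gos <= 3) + rnorm(n) - 0.5)
  ev <- evaluate_probabilities(p, y, gos)
  expect_s3_class(ev, "model_evaluation")
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_true(ev$auc_ci["lo"] <= ev$auc && ev$auc <= ev$auc_ci["hi"])
  expect_equal(sum(ev$calibration$n), n)
  expect_equal(sum(ev$misclass_by_gos$total), n)
  expect_equal(ev$accuracy, mean((p > ev$cutoff) == (gos <= 3)))
})
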