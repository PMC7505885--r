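test_that("intercept-only fit returns the log-odds of prevalence", {
  y <- c(rep(1, 20), rep(0, 25))
  fit <- fit_logistic(NULL, y)
  expect_equal(fit$intercept, log(20 / 25), tolerance = 1e-8)
  expect_equal(predict_probability(fit, numeric(0)), 20 / 45,
               tolerance = 1e-8)
})

test_that("single-binary-feature fit reproduces the 2x2 log odds ratio", {
  # exposed: 8 positive, 2 negative; unexposed: 4 positive, 6 negative
  x <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "exposed"))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coefficients["exposed"]), log(6), tolerance = 1e-6)
  # saturated model reproduces the cell proportions
  expect_equal(unname(predict_probability(fit, c(exposed = 1))), 0.8,
               tolerance = 1e-6)
  expect_equal(unname(predict_probability(fit, c(exposed = 0))), 0.4,
               tolerance = 1e-6)
})

test_that("fit matches glm on random problems to 1e-6", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 80
    m <- sample(2:5, 1)
    x <- matrix(rnorm(n * m), n, m,
                dimnames = list(NULL, paste0("f", 1:m)))
    eta <- drop(x %*% rnorm(m, 0, 0.8))
    y <- rbinom(n, 1, plogis(eta))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    fit <- fit_logistic(x, y)
    oracle <- glm.fit(cbind(1, x), y, family = binomial(),
                      control = glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$intercept), unname(oracle$coefficients[1]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients[-1]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate designs are rejected or stabilized", {
  y <- rep(c(0, 1), 10)
  xconst <- matrix(1, 20, 1, dimnames = list(NULL, "flat"))
  expect_error(fit_logistic(xconst, y), "zero-variance.*flat")
  expect_error(fit_logistic(matrix(rnorm(4), 2, 2), c(0, 1)),
               "2 rows in each")
  # complete separation: ridge-stabilized finite fit with a warning
  xsep <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1,
                 dimnames = list(NULL, "sep"))
  ysep <- rep(c(0, 1), each = 10)
  expect_message(fit <- fit_logistic(xsep, ysep), "separation")
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  expect_gt(fit$ridge, 0)
  p <- predict_probability(fit, c(sep = 5))
  expect_gt(p, 0.99)
})

test_that("predicted probabilities are monotone in the linear predictor", {
  fit <- structure(list(intercept = 0, coefficients = c(x = 1),
                        center = 0, scale = 1, feature_names = "x"),
                   class = "tbi_logit")
  xs <- seq(-10, 10, by = 0.5)
  ps <- vapply(xs, function(v) predict_probability(fit, c(x = v)),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_equal(ps[xs == 0], 0.5)
  expect_lt(abs(ps[length(ps)] - 1), 1e-4)
  expect_error(predict_probability(fit, c(z = 1)), "missing model features")
})

test_that("forward selection fixes the risk score first, then the signal", {
  tm <- toy_matrix()
  ord <- ffs_order(tm$x, tm$y)
  expect_equal(ord[1], "crash_risk")
  expect_equal(ord[2], "signal")
  expect_setequal(ord, colnames(tm$x))
})

test_that("a duplicated column adds no criterion and falls to the end", {
  tm <- toy_matrix()
  x <- cbind(tm$x, signal_dup = tm$x[, "signal"])
  ord <- ffs_order(x, tm$y)
  expect_equal(ord[2], "signal")
  # the duplicate gains nothing over noise; it must not follow immediately
  # by criterion, only by tie-break order, so just check it is not second
  expect_false(ord[2] == "signal_dup")
})

test_that("rank aggregation reproduces the worked modal example", {
  folds <- list(c("A", "B", "C"), c("A", "C", "B"), c("B", "A", "C"))
  cr <- aggregate_rankings(folds)
  expect_equal(cr$ordering, c("A", "B", "C"))
  # winners A, B, C collect 2, 1 and 2 position votes respectively
  expect_equal(unname(cr$vote_counts), c(2L, 1L, 2L))
  # identical folds return the common ordering with full votes
  same <- aggregate_rankings(rep(list(c("X", "Y", "Z")), 45))
  expect_equal(same$ordering, c("X", "Y", "Z"))
  expect_equal(unname(same$vote_counts), c(45, 45, 45))
  # a single deviant fold cannot override the majority
  folds45 <- c(rep(list(c("A", "B", "C")), 44), list(c("C", "B", "A")))
  expect_equal(aggregate_rankings(folds45)$ordering, c("A", "B", "C"))
  expect_error(aggregate_rankings(list(c("A", "B"), c("A", "X"))),
               "permutations")
})

test_that("out-of-fold probabilities are honest and row-order invariant", {
  tm <- toy_matrix(n = 40)
  ranking <- c("crash_risk", "signal", "noise1", "noise2")
  p <- loocv_probabilities(tm$x, tm$y, ranking, 2)
  expect_length(p, 40)
  expect_true(all(p > 0 & p < 1))
  # manual fold check
  fit1 <- fit_logistic(tm$x[-1, c("crash_risk", "signal")], tm$y[-1])
  expect_equal(p[1], unname(predict_probability(
    fit1, tm$x[1, c("crash_risk", "signal")])), tolerance = 1e-10)
  # permuting rows permutes the probabilities identically
  set.seed(8)
  perm <- sample(40)
  p2 <- loocv_probabilities(tm$x[perm, ], tm$y[perm], ranking, 2)
  expect_equal(p2, p[perm], tolerance = 1e-8)
})

test_that("a separable feature drives out-of-fold AUC near 1 at n=100", {
  set.seed(12)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(crash_risk = plogis(rnorm(n) + 0.5 * y),
             sep = y + rnorm(n, 0, 0.05))
  p <- suppressMessages(
    loocv_probabilities(x, y, c("crash_risk", "sep"), 2))
  expect_gte(roc_auc(p, y)$auc, 0.95)
})

test_that("best model size is the AUC argmax with small-size tie-break", {
  expect_equal(select_best_size(
    c(`1` = 0.76, `2` = 0.80, `3` = 0.82, `4` = 0.85, `5` = 0.90,
      `6` = 0.88)), 5)
  expect_equal(select_best_size(c(`1` = 0.7, `2` = 0.7, `3` = 0.7)), 1)
  expect_equal(select_best_size(
    c(`1` = 0.1, `2` = 0.2, `3` = 0.3, `4` = 0.4, `5` = 0.5, `6` = 0.6)), 6)
  # sizes beyond max_size are ignored
  expect_equal(select_best_size(c(`1` = 0.6, `2` = 0.7, `7` = 0.99),
                                max_size = 6), 2)
})
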