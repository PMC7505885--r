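#' ROC curve and trapezoid AUC
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when score >= threshold), yielding ROC points from (0, 0) to (1, 1), and
#' integrates by the trapezoid rule. Tied scores contribute diagonal
#' segments, so the trapezoid area equals the tie-adjusted concordant-pair
#' (Mann-Whitney) statistic exactly.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Outcome: logical/0-1 or favourable/unfavourable factor;
#'   positive class = unfavourable.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_outcome01(labels)
  if (sum(y) == 0L || sum(1 - y) == 0L)
    stop("both outcome classes are required for an ROC curve", call. = FALSE)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y)
  n0 <- sum(1 - y)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-approximation interval from the DeLong placement-variance
#' estimate, truncated to [0, 1]. A degenerate AUC of exactly 0 or 1
#' collapses the interval to a point, with a warning. `method =
#' "bootstrap"` resamples patients with replacement instead (percentile
#' interval), as an internal cross-check.
#'
#' @param scores,labels As in [roc_auc()].
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @return List with `auc`, `lo`, `hi`, `se` (DeLong only) and `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"), n_boot = 2000L) {
  method <- match.arg(method)
  y <- as_outcome01(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes are required", call. = FALSE)
  auc <- auc_rank(scores, y)
  if (method == "bootstrap") {
    idx1 <- which(y == 1)
    idx0 <- which(y == 0)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, n1, replace = TRUE),
             sample(idx0, n0, replace = TRUE))
      auc_rank(scores[i], y[i])
    }, numeric(1))
    q <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    return(list(auc = auc, lo = q[1], hi = q[2], se = stats::sd(bs),
                level = level))
  }
  v10 <- vapply(pos, function(p)
    (sum(p > neg) + 0.5 * sum(p == neg)) / n0, numeric(1))
  v01 <- vapply(neg, function(q)
    (sum(pos > q) + 0.5 * sum(pos == q)) / n1, numeric(1))
  s2 <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (auc %in% c(0, 1) || s2 == 0) {
    warning("degenerate AUC; confidence interval collapses to a point")
    return(list(auc = auc, lo = auc, hi = auc, se = 0, level = level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(s2)
  list(auc = auc, lo = max(0, auc - z * se), hi = min(1, auc + z * se),
       se = se, level = level)
}

#' Youden-index cutoff and accuracy
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' scores, plus sentinels below the minimum and above the maximum
#' (classify-all-positive / classify-all-negative). The cutoff maximizing
#' Youden's J = sensitivity + specificity - 1 is chosen; exact ties go to
#' the lowest cutoff, favouring sensitivity. A patient is predicted
#' unfavourable when score > cutoff. Accuracy is the fraction correctly
#' classified at the chosen cutoff.
#'
#' @param scores,labels As in [roc_auc()].
#' @return List with `cutoff`, `youden`, `accuracy`, `sensitivity`,
#'   `specificity` and `predicted` (0/1 vector).
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_outcome01(labels)
  if (sum(y) == 0L || sum(1 - y) == 0L)
    stop("both outcome classes are required", call. = FALSE)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1,
            if (length(u) > 1) (utils::head(u, -1) + utils::tail(u, -1)) / 2,
            u[length(u)] + 1)
  stats_at <- function(ct) {
    pred <- as.numeric(scores > ct)
    sens <- sum(pred == 1 & y == 1) / sum(y)
    spec <- sum(pred == 0 & y == 0) / sum(1 - y)
    c(sens = sens, spec = spec, j = sens + spec - 1,
      acc = mean(pred == y))
  }
  st <- vapply(cand, stats_at, numeric(4))
  jmax <- max(st["j", ])
  best <- which(st["j", ] >= jmax - 1e-12)[1L]   # lowest cutoff wins ties
  cutoff <- cand[best]
  list(cutoff = cutoff,
       youden = unname(st["j", best]),
       accuracy = unname(st["acc", best]),
       sensitivity = unname(st["sens", best]),
       specificity = unname(st["spec", best]),
       predicted = as.numeric(scores > cutoff))
}

#' Calibration bins
#'
#' Equal-width bins on [0, 1]; for each non-empty bin, the mean predicted
#' probability, the observed positive fraction and the count. The last bin
#' is closed at 1.
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param labels As in [roc_auc()].
#' @param n_bins Number of bins (>= 2, default 5).
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_predicted`,
#'   `observed_fraction`, `n`; empty bins omitted, counts summing to the
#'   number of patients.
#' @export
calibration_bins <- function(probabilities, labels, n_bins = 5L) {
  stopifnot(n_bins >= 2L, all(probabilities >= 0 & probabilities <= 1))
  y <- as_outcome01(labels)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(probabilities, edges, rightmost.closed = TRUE),
              n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mean_predicted = mean(probabilities[sel]),
               observed_fraction = mean(y[sel]),
               n = sum(sel))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Misclassifications stratified by true GOS
#'
#' Counts wrong predictions per true GOS level: a prediction is wrong when
#' it is favourable for GOS 1-3 (false favourable) or unfavourable for GOS
#' 4-5 (false unfavourable).
#'
#' @param predicted Predicted class: 0/1 (1 = unfavourable), logical, or
#'   the outcome factor.
#' @param gos True GOS values, integers in 1..5.
#' @return data.frame with `gos`, `wrong`, `total` for levels 1..5.
#' @export
misclassification_by_gos <- function(predicted, gos) {
  pred <- as_outcome01(predicted)
  if (any(is.na(gos)) || any(gos != round(gos)) || any(gos < 1) ||
      any(gos > 5))
    stop("gos values must be integers in 1..5", call. = FALSE)
  stopifnot(length(pred) == length(gos))
  truth <- as.numeric(gos <= 3)
  data.frame(
    gos = 1:5,
    wrong = vapply(1:5, function(g)
      sum(gos == g & pred != truth), integer(1)),
    total = vapply(1:5, function(g) sum(gos == g), integer(1))
  )
}

#' Full evaluation of out-of-fold probabilities
#'
#' Bundles [roc_auc()], [auc_ci()], [youden_cutoff()],
#' [calibration_bins()] and [misclassification_by_gos()] into one report.
#'
#' @param probabilities Out-of-fold probabilities of unfavourable outcome.
#' @param labels As in [roc_auc()].
#' @param gos True GOS values (1..5), aligned with `probabilities`.
#' @param config A [pipeline_config()] (calibration bin count, CI method).
#' @return Object of class `model_evaluation`.
#' @export
evaluate_probabilities <- function(probabilities, labels, gos,
                                   config = pipeline_config()) {
  roc <- roc_auc(probabilities, labels)
  ci <- auc_ci(probabilities, labels, method = config$ci_method)
  yc <- youden_cutoff(probabilities, labels)
  structure(
    list(probabilities = probabilities,
         roc_points = roc$points,
         auc = roc$auc,
         auc_ci = c(lo = ci$lo, hi = ci$hi),
         cutoff = yc$cutoff,
         accuracy = yc$accuracy,
         sensitivity = yc$sensitivity,
         specificity = yc$specificity,
         calibration = calibration_bins(probabilities, labels,
                                        config$calibration_bins),
         misclass_by_gos = misclassification_by_gos(yc$predicted, gos)),
    class = "model_evaluation"
  )
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "<model_evaluation: n=%d, AUC %.3f (%.3f-%.3f), cutoff %.3f, accuracy %.1f%%>\n",
    length(x$probabilities), x$auc, x$auc_ci["lo"], x$auc_ci["hi"],
    x$cutoff, 100 * x$accuracy))
  invisible(x)
}
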