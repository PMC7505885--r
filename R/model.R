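#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit on training-standardized features
#' (per-feature mean/SD), converged when the largest coefficient update
#' falls below `tol` or after `max_iter` Newton steps. Coefficients are
#' back-transformed to raw units for reporting; prediction uses the raw-unit
#' form, so standardization is purely numerical. Complete separation (the
#' fit diverging or failing to converge) is handled by restarting with a
#' tiny L2 penalty (1e-8), escalated tenfold until convergence, with a
#' warning — the out-of-fold machinery on small cohorts with strong features
#' will hit separation and must return a finite, deterministic fit.
#'
#' @param x Numeric matrix (n x m, m >= 0) with column names; no missing
#'   entries; no zero-variance column.
#' @param y Outcome: logical/0-1 vector, or the factor produced by
#'   [dichotomize_gos()] (positive class `unfavourable`).
#' @param tol Convergence tolerance on the max absolute coefficient update.
#' @param max_iter Maximum Newton iterations per attempt.
#' @return Object of class `tbi_logit`: `intercept` and `coefficients` in
#'   raw units, the standardization (`center`, `scale`), `feature_names`,
#'   `fitted` (training probabilities), `ridge` (0 unless separation
#'   handling engaged) and `converged`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  y <- as_outcome01(y)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("fit_logistic needs at least 2 rows in each outcome class",
         call. = FALSE)
  if (anyNA(x)) stop("missing entries in the feature matrix", call. = FALSE)
  m <- ncol(x)
  if (m > 0L) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    if (any(scl == 0))
      stop("zero-variance feature: ",
           paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
    xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  } else {
    ctr <- scl <- numeric(0)
    xs <- x
  }
  Xd <- cbind(1, xs)
  fit <- irls_core(Xd, y, tol = tol, max_iter = max_iter)
  if (fit$lambda > 0)
    log_warn(sprintf(
      "separation detected; logistic fit stabilized with L2 penalty %g",
      fit$lambda))

  beta <- fit$beta
  if (m > 0L) {
    coef_raw <- beta[-1L] / scl
    intercept <- beta[1L] - sum(beta[-1L] * ctr / scl)
    names(coef_raw) <- colnames(x)
  } else {
    coef_raw <- stats::setNames(numeric(0), character(0))
    intercept <- beta[1L]
  }
  structure(
    list(intercept = unname(intercept),
         coefficients = coef_raw,
         center = ctr, scale = scl,
         feature_names = colnames(x) %||% character(0),
         fitted = fit$p,
         ridge = fit$lambda,
         converged = TRUE),
    class = "tbi_logit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Newton/IRLS core on a prebuilt design matrix (first column = intercept).
# Standardize columns before calling: the escalating tiny-L2 separation
# fallback assumes comparable scales. Warm starts cut iterations inside the
# greedy selection loop.
irls_core <- function(Xd, y, beta0 = NULL, tol = 1e-8, max_iter = 100L,
                      beta_cap = 1e6) {
  m1 <- ncol(Xd)
  pen <- c(0, rep(1, m1 - 1L))       # intercept never penalized
  if (is.null(beta0)) beta0 <- c(stats::qlogis(mean(y)), rep(0, m1 - 1L))
  lambda <- 0
  repeat {
    beta <- beta0
    done <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(Xd %*% beta)
      p <- stats::plogis(eta)
      w <- p * (1 - p)
      w[w < 1e-10] <- 1e-10
      g <- crossprod(Xd, y - p) - lambda * pen * beta
      H <- crossprod(Xd * w, Xd)
      if (lambda > 0) H <- H + diag(lambda * pen, m1)
      delta <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) break
      beta <- beta + drop(delta)
      # past the cap the likelihood is flat to machine precision: treat as
      # separated and escalate the penalty instead of iterating on
      if (any(!is.finite(beta)) || max(abs(beta)) > beta_cap) break
      if (max(abs(delta)) < tol) { done <- TRUE; break }
    }
    if (done)
      return(list(beta = beta, p = stats::plogis(drop(Xd %*% beta)),
                  lambda = lambda))
    lambda <- if (lambda == 0) 1e-8 else lambda * 10
    if (lambda > 1e2)
      stop("logistic fit failed to converge even with heavy ridge",
           call. = FALSE)
  }
}

# Column standardization without sweep()/apply() overhead.
standardize_cols <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  v <- colMeans(x * x) - ctr^2
  scl <- sqrt(pmax(v, 0) * n / (n - 1))
  if (any(scl == 0))
    stop("zero-variance feature: ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  list(xs = (x - rep(ctr, each = n)) / rep(scl, each = n),
       center = ctr, scale = scl)
}

# Accept logical, 0/1 numeric or the outcome factor; positive class = 1 =
# unfavourable outcome.
as_outcome01 <- function(y) {
  if (is.factor(y)) {
    if (!all(levels(y) %in% c("favourable", "unfavourable")))
      stop("outcome factor must have levels favourable/unfavourable",
           call. = FALSE)
    return(as.numeric(y == "unfavourable"))
  }
  if (is.logical(y)) return(as.numeric(y))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("outcome must be 0/1, logical, or favourable/unfavourable",
         call. = FALSE)
  y
}

#' Predicted probability of unfavourable outcome
#'
#' @param model A `tbi_logit` from [fit_logistic()].
#' @param row Named numeric vector, single-row matrix or data.frame covering
#'   the model's features.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
predict_probability <- function(model, row) {
  stopifnot(inherits(model, "tbi_logit"))
  fn <- model$feature_names
  if (length(fn) == 0L)
    return(stats::plogis(model$intercept))
  if (is.data.frame(row)) row <- as.matrix(row)
  if (is.null(dim(row))) row <- matrix(row, nrow = 1,
                                       dimnames = list(NULL, names(row)))
  if (!all(fn %in% colnames(row)))
    stop("row is missing model features: ",
         paste(setdiff(fn, colnames(row)), collapse = ", "), call. = FALSE)
  x <- row[, fn, drop = FALSE]
  if (anyNA(x)) stop("missing feature values in prediction row",
                     call. = FALSE)
  stats::plogis(model$intercept + drop(x %*% model$coefficients))
}

# Fast tie-adjusted rank AUC (Mann-Whitney), positive class = 1.
auc_rank <- function(scores, y01) {
  n1 <- sum(y01)
  n0 <- length(y01) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC",
                                 call. = FALSE)
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Forward feature selection order
#'
#' Greedy forward selection of all columns: position 1 is `fixed_first`
#' (the risk score, by design of the procedure); each further position adds the
#' candidate maximizing the in-sample criterion of the refitted logistic
#' model on the training rows (`"auc"` by default, `"deviance"` as the
#' alternative), until every column is ordered. Exact criterion ties are
#' broken by the larger single-feature AUC, then lexicographically.
#'
#' @param x Feature matrix with named columns.
#' @param y Outcome (see [fit_logistic()]).
#' @param fixed_first Column fixed at position 1 (default `"crash_risk"`).
#' @param criterion `"auc"` or `"deviance"`.
#' @return Character vector: all column names, best to worst.
#' @export
ffs_order <- function(x, y, fixed_first = "crash_risk",
                      criterion = c("auc", "deviance")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  y01 <- as_outcome01(y)
  nm <- colnames(x)
  if (!fixed_first %in% nm)
    stop("fixed_first '", fixed_first, "' is not a column of x",
         call. = FALSE)
  single_auc <- vapply(nm, function(f) {
    a <- auc_rank(x[, f], y01)
    max(a, 1 - a)
  }, numeric(1))
  std <- standardize_cols(x)
  xs <- std$xs
  n <- nrow(xs)
  ones <- rep(1, n)
  selected <- fixed_first
  remaining <- setdiff(nm, fixed_first)
  beta_sel <- NULL                      # warm start: winner of previous step
  while (length(remaining) > 0L) {
    # a huge (separation-stabilized) previous beta is a bad Newton start
    warm <- if (is.null(beta_sel) || max(abs(beta_sel)) > 10) NULL else
      c(beta_sel, 0)
    # selection only needs ordering of in-sample criteria: a tight Newton
    # budget and a low divergence cap (standardized coefficients beyond ~30
    # are numerically saturated) make separated candidates cheap
    fits <- lapply(remaining, function(f) {
      irls_core(cbind(ones, xs[, c(selected, f), drop = FALSE]), y01,
                beta0 = warm, max_iter = 25L, beta_cap = 30)
    })
    crit <- vapply(fits, function(fit) {
      if (criterion == "auc") auc_rank(fit$p, y01)
      else -binomial_deviance(y01, fit$p)
    }, numeric(1))
    best <- max(crit)
    ties <- which(crit >= best - 1e-12)
    if (length(ties) > 1L) {
      cnd <- remaining[ties]
      pick <- ties[order(-single_auc[cnd], cnd)][1L]
    } else pick <- ties
    beta_sel <- fits[[pick[1L]]]$beta
    selected <- c(selected, remaining[pick[1L]])
    remaining <- remaining[-pick[1L]]
  }
  selected
}

binomial_deviance <- function(y01, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y01 * log(p) + (1 - y01) * log(1 - p))
}

#' Consensus ranking by position-wise modal vote
#'
#' Aggregates per-fold orderings into one consensus: the position-k winner
#' is the name occurring most often at position k across folds, excluding
#' names already placed at earlier positions; ties (including the
#' zero-votes case) are broken by the smaller mean rank across folds, then
#' lexicographically. Continues until all names are placed.
#'
#' @param per_fold_orderings List of character vectors, each a permutation
#'   of one common name set (e.g. from [ffs_order()] per leave-one-out
#'   fold).
#' @return Object of class `consensus_ranking`: `ordering`, `vote_counts`
#'   (votes received by each winner at its position), `mean_ranks`, and
#'   `per_fold` (the audit trail).
#' @export
aggregate_rankings <- function(per_fold_orderings) {
  stopifnot(is.list(per_fold_orderings), length(per_fold_orderings) >= 1L)
  nms <- sort(per_fold_orderings[[1L]])
  for (o in per_fold_orderings)
    if (!identical(sort(o), nms))
      stop("per-fold orderings must be permutations of one name set",
           call. = FALSE)
  n_par <- length(nms)
  rank_mat <- vapply(per_fold_orderings, function(o) match(nms, o),
                     integer(n_par))
  rank_mat <- matrix(rank_mat, nrow = n_par,
                     dimnames = list(nms, NULL))
  mean_ranks <- rowMeans(rank_mat)
  ordering <- character(n_par)
  votes <- integer(n_par)
  remaining <- nms
  for (k in seq_len(n_par)) {
    at_k <- vapply(per_fold_orderings, `[`, character(1), k)
    v <- vapply(remaining, function(nm) sum(at_k == nm), integer(1))
    cand <- remaining[v == max(v)]
    if (length(cand) > 1L)
      cand <- cand[order(mean_ranks[cand], cand)]
    ordering[k] <- cand[1L]
    votes[k] <- max(v)
    remaining <- setdiff(remaining, cand[1L])
  }
  structure(
    list(ordering = ordering,
         vote_counts = stats::setNames(votes, ordering),
         mean_ranks = mean_ranks,
         per_fold = per_fold_orderings),
    class = "consensus_ranking"
  )
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("<consensus_ranking>\n")
  cat(sprintf("  %2d. %-12s (%d/%d votes)\n", seq_along(x$ordering),
              x$ordering, x$vote_counts, length(x$per_fold)), sep = "")
  invisible(x)
}

#' Fold-wise forward-selection orderings
#'
#' Runs [ffs_order()] once per leave-one-out fold (training on all rows but
#' one) and returns the per-fold orderings, ready for
#' [aggregate_rankings()].
#'
#' @inheritParams ffs_order
#' @return List of orderings, one per row of `x`.
#' @export
loocv_ffs_orderings <- function(x, y, fixed_first = "crash_risk",
                                criterion = c("auc", "deviance")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  y01 <- as_outcome01(y)
  lapply(seq_len(nrow(x)), function(i)
    ffs_order(x[-i, , drop = FALSE], y01[-i], fixed_first, criterion))
}

#' Out-of-fold probabilities for a model of given size
#'
#' Leave-one-out assembly: for each row, fits the logistic model with the
#' top-`m` consensus-ranked parameters (the risk score is parameter 1 by
#' construction) on all other rows and predicts the held-out row. The result
#' is one honest out-of-fold probability of unfavourable outcome per
#' patient.
#'
#' @param x Feature matrix with named columns.
#' @param y Outcome (see [fit_logistic()]).
#' @param ranking A `consensus_ranking` or character vector of ordered
#'   names.
#' @param m Model size, `1 <= m <= length(ranking)`.
#' @return Numeric vector of length `nrow(x)`.
#' @export
loocv_probabilities <- function(x, y, ranking, m) {
  if (inherits(ranking, "consensus_ranking")) ranking <- ranking$ordering
  stopifnot(m >= 1L, m <= length(ranking))
  x <- as.matrix(x)
  y01 <- as_outcome01(y)
  feats <- ranking[seq_len(m)]
  if (!all(feats %in% colnames(x)))
    stop("ranking names absent from the feature matrix", call. = FALSE)
  vapply(seq_len(nrow(x)), function(i) {
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2L)
      stop("single-class training labels in a leave-one-out fold",
           call. = FALSE)
    fit <- fit_logistic(x[-i, feats, drop = FALSE], ytr)
    predict_probability(fit, x[i, feats, drop = FALSE])
  }, numeric(1))
}

#' Best model size by out-of-fold AUC
#'
#' @param per_size_auc Named numeric: AUC per model size (names coercible to
#'   integer sizes).
#' @param max_size Largest size to consider.
#' @return The size with the highest AUC among those `<= max_size`; ties go
#'   to the smallest size.
#' @export
select_best_size <- function(per_size_auc, max_size = 6L) {
  sizes <- as.integer(names(per_size_auc))
  if (anyNA(sizes)) stop("per_size_auc must be named by integer sizes",
                         call. = FALSE)
  keep <- sizes <= max_size
  sizes <- sizes[keep]
  aucs <- as.numeric(per_size_auc[keep])
  ord <- order(-aucs, sizes)
  sizes[ord][1L]
}
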