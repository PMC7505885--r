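#' Run the full analysis for one cumulative period
#'
#' From an already-built feature matrix: keeps the included rows, derives
#' the consensus parameter ranking (fold-wise forward selection with the
#' risk score fixed first, then position-wise modal aggregation), assembles
#' out-of-fold probabilities for model sizes 1..`max_total_parameters`, and
#' evaluates the risk-score-only model (size 1) and the best combined model
#' (the size >= 2 with the highest out-of-fold AUC; ties to the smaller
#' size).
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param config A [pipeline_config()].
#' @return Object of class `segment_result`: `segment_end_hours`, `n`,
#'   `ranking`, `per_size_auc`, `best_size`, `crash_eval`, `best_eval`,
#'   `feature_matrix`.
#' @export
run_segment <- function(fm, config = pipeline_config()) {
  seg <- fm$segment_end_hours[1L]
  inc <- fm[fm$included, , drop = FALSE]
  if (nrow(inc) == 0L) {
    log_warn(sprintf("0-%g h period: every patient excluded; period skipped",
                     seg))
    return(NULL)
  }
  y <- factor(inc$outcome, levels = c("favourable", "unfavourable"))
  if (length(unique(inc$outcome)) < 2L)
    stop(sprintf("0-%g h period: single-class outcome among included patients",
                 seg), call. = FALSE)
  x <- as.matrix(inc[, parameter_names()])
  rownames(x) <- inc$patient_id

  ranking <- aggregate_rankings(
    loocv_ffs_orderings(x, y, fixed_first = "crash_risk",
                        criterion = config$ffs_criterion))

  sizes <- seq_len(min(config$max_total_parameters, ncol(x)))
  probs <- lapply(sizes, function(m) loocv_probabilities(x, y, ranking, m))
  per_size_auc <- stats::setNames(
    vapply(probs, function(p) roc_auc(p, y)$auc, numeric(1)),
    sizes)

  combined_sizes <- per_size_auc[sizes >= 2L]
  best_size <- if (length(combined_sizes) > 0)
    select_best_size(combined_sizes, config$max_total_parameters) else 1L

  structure(
    list(segment_end_hours = seg,
         n = nrow(inc),
         ranking = ranking,
         per_size_auc = per_size_auc,
         best_size = best_size,
         crash_eval = evaluate_probabilities(probs[[1L]], y, inc$gos,
                                             config),
         best_eval = evaluate_probabilities(probs[[which(sizes == best_size)]],
                                            y, inc$gos, config),
         feature_matrix = fm),
    class = "segment_result"
  )
}

#' @export
print.segment_result <- function(x, ...) {
  cat(sprintf("<segment_result 0-%g h, n=%d>\n", x$segment_end_hours, x$n))
  cat(sprintf("  risk score only : AUC %.3f, accuracy %.1f%%\n",
              x$crash_eval$auc, 100 * x$crash_eval$accuracy))
  cat(sprintf("  combined (m=%d) : AUC %.3f, accuracy %.1f%%\n",
              x$best_size, x$best_eval$auc, 100 * x$best_eval$accuracy))
  cat("  ranking:", paste(x$ranking$ordering[seq_len(min(6,
      length(x$ranking$ordering)))], collapse = " > "), "...\n")
  invisible(x)
}

#' Run the full pipeline on a cohort
#'
#' Executes preprocessing ([derive_channels()]), index computation
#' ([compute_indices()]), feature extraction and inclusion rules
#' ([build_feature_matrix()]), consensus ranking and out-of-fold modelling
#' ([run_segment()]) for every configured cumulative period. Deterministic
#' given cohort and configuration: no randomness enters after generation.
#'
#' @param cohort List of [patient_record()] objects (>= 10, both outcome
#'   classes present).
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: list of `segment_result`s
#'   (skipped periods omitted), named `"6h"`, `"12h"`, ...
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(length(cohort) >= 10L)
  outcomes <- vapply(cohort, function(r)
    as.character(dichotomize_gos(r$gos)), character(1))
  if (length(unique(outcomes)) < 2L)
    stop("cohort has a single outcome class", call. = FALSE)

  log_info(sprintf("deriving channels and indices for %d patients",
                   length(cohort)))
  derived <- lapply(cohort, derive_channels, config = config)
  idx <- lapply(derived, compute_indices, config = config)

  ends <- config$segment_ends_hours
  prev <- c(0, utils::head(ends, -1))
  results <- list()
  for (s in seq_along(ends)) {
    fm <- build_feature_matrix(cohort, derived, idx, ends[s], prev[s],
                               config)
    sr <- run_segment(fm, config)
    if (!is.null(sr)) results[[sprintf("%gh", ends[s])]] <- sr
  }
  structure(results, class = "pipeline_result")
}

#' Write every report of a pipeline run
#'
#' Writes, per period, the consensus ranking (`ranking_<seg>.json`), the
#' risk-score-only and best combined evaluations (`eval_crash_<seg>.json`,
#' `eval_combined_<seg>.json`), the feature matrix
#' (`features_<seg>.csv`), ROC and calibration point lists (CSV), plus a
#' cohort-level `summary.json` mirroring the headline table (AUC, CI,
#' accuracy per period and model).
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  for (nm in names(result)) {
    sr <- result[[nm]]
    write_report(sr$ranking, file.path(dir, sprintf("ranking_%s.json", nm)))
    write_report(sr$crash_eval,
                 file.path(dir, sprintf("eval_crash_%s.json", nm)))
    write_report(sr$best_eval,
                 file.path(dir, sprintf("eval_combined_%s.json", nm)))
    write_report(sr$feature_matrix,
                 file.path(dir, sprintf("features_%s.csv", nm)))
    write_report(sr$best_eval$roc_points,
                 file.path(dir, sprintf("roc_combined_%s.csv", nm)))
    write_report(sr$best_eval$calibration,
                 file.path(dir, sprintf("calibration_combined_%s.csv", nm)))
    summary[[nm]] <- list(
      n = sr$n,
      crash_auc = sr$crash_eval$auc,
      crash_auc_ci = as.list(sr$crash_eval$auc_ci),
      crash_accuracy_pct = 100 * sr$crash_eval$accuracy,
      combined_size = sr$best_size,
      combined_auc = sr$best_eval$auc,
      combined_auc_ci = as.list(sr$best_eval$auc_ci),
      combined_accuracy_pct = 100 * sr$best_eval$accuracy,
      combined_parameters =
        sr$ranking$ordering[seq_len(sr$best_size)],
      per_size_auc = as.list(sr$per_size_auc))
  }
  write_json_report(summary, file.path(dir, "summary.json"))
  invisible(dir)
}
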