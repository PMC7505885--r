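#' Read a cohort from disk
#'
#' Loads `metadata_path` (CSV with columns `patient_id`, `crash_risk`,
#' `gos`, `abp_zero_level`) and, for every row, the signal file
#' `<patient_id>.csv` in `signals_dir` with columns `time_s`, `abp_mmHg`,
#' `icp_mmHg`, `hr_bpm` and optionally `amp_mmHg`. The time column must be
#' a uniform grid (verified; gaps are blank cells, never skipped rows). A
#' `crash_risk` column containing values above 1 is interpreted as percent
#' and divided by 100, so both conventions load to the internal [0, 1]
#' probability.
#'
#' @param signals_dir Directory of per-patient signal CSVs.
#' @param metadata_path Path to the cohort metadata CSV.
#' @return List of [patient_record()] objects.
#' @export
read_cohort <- function(signals_dir, metadata_path) {
  meta <- as.data.frame(data.table::fread(metadata_path,
                                          na.strings = c("", "NA")))
  need <- c("patient_id", "crash_risk", "gos", "abp_zero_level")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(meta$crash_risk > 1, na.rm = TRUE)) {
    log_info("crash_risk read as percent; dividing by 100")
    meta$crash_risk <- meta$crash_risk / 100
  }
  lapply(seq_len(nrow(meta)), function(i) {
    id <- as.character(meta$patient_id[i])
    path <- file.path(signals_dir, paste0(id, ".csv"))
    if (!file.exists(path))
      stop(sprintf("missing signal file for patient %s: %s", id, path),
           call. = FALSE)
    sig <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
    scols <- c("time_s", "abp_mmHg", "icp_mmHg", "hr_bpm")
    if (!all(scols %in% names(sig)))
      stop(sprintf("patient %s: signal CSV must have columns %s", id,
                   paste(scols, collapse = ", ")), call. = FALSE)
    tt <- sig$time_s
    if (length(tt) < 2L)
      stop(sprintf("patient %s: signal CSV needs >= 2 rows", id),
           call. = FALSE)
    dt <- diff(tt)
    interval <- stats::median(dt)
    if (any(abs(dt - interval) > 1e-6 * max(1, interval)))
      stop(sprintf("patient %s: non-uniform time grid (gaps must be blank cells on the grid)",
                   id), call. = FALSE)
    tr <- function(col, ch) signal_trace(sig[[col]], interval, tt[1], ch)
    amp <- if ("amp_mmHg" %in% names(sig) &&
               !all(is.na(sig$amp_mmHg))) tr("amp_mmHg", "amp") else NULL
    patient_record(id,
                   abp = tr("abp_mmHg", "abp"),
                   icp = tr("icp_mmHg", "icp"),
                   hr = tr("hr_bpm", "hr"),
                   crash_risk = meta$crash_risk[i],
                   gos = meta$gos[i],
                   abp_zero_level = as.character(meta$abp_zero_level[i]),
                   amp = amp)
  })
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: writes `cohort.csv` plus one signal CSV per
#' patient into `dir` (created if needed). Numeric signal values are
#' written with six decimal places (the declared precision of the
#' interchange dialect); missing values are empty cells; separator comma,
#' decimal dot, UTF-8, header row.
#'
#' @param records List of [patient_record()] objects.
#' @param dir Output directory.
#' @param truth Optional truth table (data.frame) written as `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(
    patient_id = vapply(records, `[[`, character(1), "patient_id"),
    crash_risk = vapply(records, `[[`, numeric(1), "crash_risk"),
    gos = vapply(records, `[[`, integer(1), "gos"),
    abp_zero_level = vapply(records, `[[`, character(1), "abp_zero_level"))
  data.table::fwrite(meta, file.path(dir, "cohort.csv"))
  for (rec in records) {
    df <- data.frame(time_s = round(trace_times(rec$abp), 6),
                     abp_mmHg = round(rec$abp$values, 6),
                     icp_mmHg = round(rec$icp$values, 6),
                     hr_bpm = round(rec$hr$values, 6))
    if (!is.null(rec$amp)) df$amp_mmHg <- round(rec$amp$values, 6)
    data.table::fwrite(df, file.path(dir, paste0(rec$patient_id, ".csv")))
  }
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  invisible(dir)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror [pipeline_config()] arguments;
#'   absent fields take the defaults.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if ("thresholds" %in% names(raw)) raw$thresholds <- unlist(raw$thresholds)
  do.call(pipeline_config, raw)
}

#' Write a report object
#'
#' Rankings and evaluations are written as JSON (full numeric precision);
#' feature matrices and ROC/calibration point lists as CSV. The companion
#' [read_report()] reproduces the stored object.
#'
#' @param report A `consensus_ranking`, `model_evaluation`,
#'   `segment_result`, `pipeline_result` or data.frame.
#' @param out_path Output path; use `.json` for rankings/evaluations and
#'   `.csv` for tables.
#' @return `out_path`, invisibly.
#' @export
write_report <- function(report, out_path) {
  UseMethod("write_report")
}

#' @export
write_report.data.frame <- function(report, out_path) {
  data.table::fwrite(as.data.frame(report), out_path)
  invisible(out_path)
}

write_json_report <- function(x, out_path) {
  jsonlite::write_json(x, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(out_path)
}

#' @export
write_report.consensus_ranking <- function(report, out_path) {
  write_json_report(list(type = "consensus_ranking",
                         ordering = report$ordering,
                         vote_counts = as.list(report$vote_counts),
                         mean_ranks = as.list(report$mean_ranks),
                         per_fold = report$per_fold), out_path)
}

#' @export
write_report.model_evaluation <- function(report, out_path) {
  write_json_report(list(type = "model_evaluation",
                         auc = report$auc,
                         auc_ci = as.list(report$auc_ci),
                         cutoff = report$cutoff,
                         accuracy = report$accuracy,
                         sensitivity = report$sensitivity,
                         specificity = report$specificity,
                         probabilities = report$probabilities,
                         roc_points = report$roc_points,
                         calibration = report$calibration,
                         misclass_by_gos = report$misclass_by_gos), out_path)
}

#' Read a report written by [write_report()]
#'
#' @param path `.json` or `.csv` report path.
#' @return The stored list (JSON) or data.frame (CSV).
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
}
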