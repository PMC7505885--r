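#!/usr/bin/env Rscript
# Out-of-fold modelling and evaluation per period: leave-one-out logistic
# models of size 1..6 over the consensus ranking, the size with the best
# out-of-fold AUC as the combined model, ROC/AUC with DeLong intervals,
# Youden cutoff accuracy, calibration bins and the misclassification-by-GOS
# table. Writes evaluation JSONs, ROC/calibration CSVs and summary.json
# under results/, and prints the headline table.
#
# Usage: Rscript analysis/04_train_evaluate.R

suppressMessages(library(tbiprog))

config <- pipeline_config()
summary_rows <- list()
for (seg in config$segment_ends_hours) {
  fpath <- file.path("results", sprintf("features_%gh.csv", seg))
  rpath <- file.path("results", sprintf("ranking_%gh.json", seg))
  if (!file.exists(fpath) || !file.exists(rpath))
    stop("run analysis/02 and analysis/03 first")
  fm <- read_report(fpath)
  ranking <- read_report(rpath)$ordering
  inc <- fm[fm$included, ]
  x <- as.matrix(inc[, parameter_names()])
  y <- factor(inc$outcome, levels = c("favourable", "unfavourable"))

  sizes <- seq_len(config$max_total_parameters)
  probs <- lapply(sizes, function(m) loocv_probabilities(x, y, ranking, m))
  aucs <- vapply(probs, function(p) roc_auc(p, y)$auc, numeric(1))
  names(aucs) <- sizes
  best <- select_best_size(aucs[-1], config$max_total_parameters)

  crash_eval <- evaluate_probabilities(probs[[1]], y, inc$gos, config)
  best_eval <- evaluate_probabilities(probs[[best]], y, inc$gos, config)

  tag <- sprintf("%gh", seg)
  write_report(crash_eval,
               file.path("results", sprintf("eval_crash_%s.json", tag)))
  write_report(best_eval,
               file.path("results", sprintf("eval_combined_%s.json", tag)))
  write_report(best_eval$roc_points,
               file.path("results", sprintf("roc_combined_%s.csv", tag)))
  write_report(best_eval$calibration,
               file.path("results", sprintf("calibration_combined_%s.csv",
                                            tag)))

  summary_rows[[tag]] <- data.frame(
    period = sprintf("0-%g h", seg), n = nrow(inc),
    crash_auc = round(crash_eval$auc, 3),
    crash_acc_pct = round(100 * crash_eval$accuracy, 1),
    combined_size = best,
    combined_auc = round(best_eval$auc, 3),
    combined_acc_pct = round(100 * best_eval$accuracy, 1))
  message(sprintf(
    "0-%g h (n=%d): CRASH AUC %.2f (acc %.1f%%) | combined m=%d AUC %.2f (acc %.1f%%)",
    seg, nrow(inc), crash_eval$auc, 100 * crash_eval$accuracy,
    best, best_eval$auc, 100 * best_eval$accuracy))
}
tab <- do.call(rbind, summary_rows)
write_report(tab, file.path("results", "model_summary.csv"))
message("wrote results/model_summary.csv")
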