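#!/usr/bin/env Rscript
# Consensus parameter ranking per period: leave-one-out forward feature
# selection with the CRASH risk score fixed first, aggregated by
# position-wise modal vote. Writes ranking_<seg>.json (ordering, votes and
# the per-fold audit trail) under results/.
#
# Usage: Rscript analysis/03_rank_parameters.R

suppressMessages(library(tbiprog))

config <- pipeline_config()
for (seg in config$segment_ends_hours) {
  path <- file.path("results", sprintf("features_%gh.csv", seg))
  if (!file.exists(path)) stop("run analysis/02_extract_features.R first")
  fm <- read_report(path)
  inc <- fm[fm$included, ]
  if (length(unique(inc$outcome)) < 2) {
    message(sprintf("0-%g h: skipped (single class)", seg))
    next
  }
  x <- as.matrix(inc[, parameter_names()])
  y <- factor(inc$outcome, levels = c("favourable", "unfavourable"))
  ranking <- aggregate_rankings(
    loocv_ffs_orderings(x, y, criterion = config$ffs_criterion))
  write_report(ranking,
               file.path("results", sprintf("ranking_%gh.json", seg)))
  message(sprintf("0-%g h consensus: %s", seg,
                  paste(ranking$ordering[1:6], collapse = " > ")))
}
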