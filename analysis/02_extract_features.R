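#!/usr/bin/env Rscript
# Read the simulated cohort back from disk, repair artifacts, build the
# 10-s / 1-per-minute channel set and the PRx/PAx/RAC/RAP indices, apply
# the period inclusion rules and extract the 15 parameters for each of the
# four cumulative periods (0-6, 0-12, 0-18, 0-24 h). Writes one feature
# table per period under results/.
#
# Usage: Rscript analysis/02_extract_features.R

suppressMessages(library(tbiprog))

cohort_dir <- file.path("results", "cohort")
stopifnot(dir.exists(cohort_dir))
records <- read_cohort(cohort_dir, file.path(cohort_dir, "cohort.csv"))
config <- pipeline_config()

derived <- lapply(records, derive_channels, config = config)
idx <- lapply(derived, compute_indices, config = config)

ends <- config$segment_ends_hours
prev <- c(0, head(ends, -1))
for (s in seq_along(ends)) {
  fm <- build_feature_matrix(records, derived, idx, ends[s], prev[s],
                             config)
  path <- file.path("results", sprintf("features_%gh.csv", ends[s]))
  write_report(fm, path)
  message(sprintf("0-%g h: %d/%d patients included -> %s",
                  ends[s], sum(fm$included), nrow(fm), path))
}
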