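Package: tbiprog
Title: Outcome Prognosis in Severe Traumatic Brain Injury from First-Day
    Neuromonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts dichotomized six-month Glasgow Outcome Scale in
    severe traumatic brain injury patients by combining a baseline
    admission risk score (CRASH) with features derived from the first 24
    hours of continuous arterial blood pressure, intracranial pressure and
    heart rate monitoring. Implements scaled-MAD artifact repair, 10-second
    window averaging, the moving-correlation cerebrovascular indices PRx,
    PAx, RAC and RAP, cumulative time-period feature extraction with
    data-completeness inclusion rules, a leave-one-out forward-feature-
    selection consensus ranking with the risk score fixed first, logistic
    models of increasing size with out-of-fold probability assembly, and
    ROC/AUC evaluation with DeLong intervals, Youden-index cutoffs,
    calibration bins and outcome-scale-stratified misclassification
    tables. A seeded synthetic-cohort generator emulates slow vasogenic
    pressure waves, reactivity-dependent pressure coupling, cardiac
    pulsation, gaps and artifacts so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
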