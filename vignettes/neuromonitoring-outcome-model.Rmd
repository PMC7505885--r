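---
title: "Methods: outcome prognosis from first-day neuromonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome prognosis from first-day neuromonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbiprog)
```

## The model

Severe-TBI patients carry an admission-based risk of unfavourable
six-month outcome (dichotomized Glasgow Outcome Scale: GOS 1–3
unfavourable, 4–5 favourable; unfavourable is the positive class
throughout). The question this package operationalizes: does the first day
of continuous ABP/ICP/HR monitoring add prognostic information over that
baseline risk, and which monitoring-derived parameters carry it?

The statistical backbone is a logistic model for
\(\Pr(\text{unfavourable})\) over a subset of 15 parameters, with the
subset chosen by a two-stage leave-one-out procedure:

1. **Fold-wise forward selection.** For each of the \(n\) LOOCV folds,
   greedy forward feature selection orders all 15 parameters on the
   training rows, with the baseline risk score fixed at position 1 by
   design — the question is what monitoring adds *on top of* admission
   risk. The greedy criterion is the in-sample AUC of the refitted model
   (the procedure's end metric; binomial deviance is available via
   `pipeline_config(ffs_criterion = "deviance")`). Exact criterion ties
   fall back to the larger single-feature AUC, then the lexicographic
   name, so the ordering is deterministic.
2. **Modal consensus.** The position-\(k\) consensus parameter is the most
   frequent position-\(k\) parameter across folds, excluding those already
   placed; ties (including zero-vote positions) go to the smaller mean
   rank across folds, then lexicographic. This "column-wise vote" is
   order-dependent by construction and deliberately simple; it is not a
   general rank-aggregation optimum.
3. **Out-of-fold probability assembly.** For sizes \(m = 1..6\) (capped at
   6 against overfitting at \(n \approx 45\)), the top-\(m\) consensus
   parameters are refitted per fold and each held-out patient receives one
   honest probability. Size 1 is the risk-score-only reference; the best
   size \(m \ge 2\) by out-of-fold AUC is the combined model. Ties go to
   the smaller size (parsimony).

Within each fit, features are standardized by training-fold mean/SD purely
for numerical conditioning (mixed scales: mmHg, unitless indices,
probabilities); reported coefficients are back-transformed to raw units.
Complete separation — inevitable in LOOCV on small cohorts with strong
features — restarts the Newton solver with an L2 penalty of 1e-8,
escalated tenfold until convergence, with a warning. The fit is validated
against `glm` to \(10^{-6}\) on regular problems in the test suite.

## Signal processing

All signal work happens on a uniform grid; gaps are missing values on the
grid and are never interpolated.

* **Artifact repair**: samples more than 6 scaled MADs (MAD × 1.4826) from
  the trace median are replaced by linear interpolation between the
  nearest unflagged neighbours (nearest value at the edges). Repair is
  applied to raw HR/ABP/ICP only; the correlation indices downstream get
  no further outlier handling, since their single samples are expected to
  be noisy.
* **10-s means**: non-overlapping, aligned to monitoring start,
  left-closed windows; a window mean is emitted only when at least 50% of
  its samples are valid (a design choice, set symmetric with the 50%
  period rule; `min_valid_fraction_per_window`).
* **AMP** (ICP pulse amplitude): per 10-s window, the peak-to-trough range
  of linearly detrended samples. The trend slope is estimated from
  neighbouring 10-s window means (centred difference; one-sided at the
  edges) rather than by in-window least squares: a sampled sine is not
  exactly orthogonal to a line, and an in-window fit tilts the residuals
  enough to overstate a pure 2.5 mmHg pulsation by ~8%, while full-window
  means average the cardiac cycle out and pass linear drift through
  exactly. Waveform input must be ≥ 4 Hz; 10-s-resolution cohorts supply a
  pre-averaged `amp_mmHg` column instead (AMP is otherwise left missing
  and the amplitude-based indices with it).
* **Indices**: PRx/PAx/RAC/RAP are trailing Pearson correlations over 30
  paired 10-s means, updated every 60 s, emitted on the shared
  1-per-minute grid (first 4 minutes are warm-up). Pairs with either value
  missing are dropped; windows with under 50% valid pairs, or zero
  variance in either channel, yield missing (correlation undefined — never
  coerced to 0).

## The 15 parameters and period rules

Per patient and cumulative period \([0, T)\), \(T \in \{6, 12, 18, 24\}\)
h: means of 1-per-minute ICP/ABP/HR and of the four indices; OLS slopes
(per hour) of PRx/PAx/RAC; impairment doses above PRx 0.35, PAx 0.25, RAC
−0.05 and ICP 2 mmHg; and the risk score. "Impairment dose" is the area
of the signal above the threshold divided by the number of samples — the
mean exceedance in signal units; the time-fraction reading common in the
monitoring literature is available via `impairment_mode = "fraction"`.
The ICP threshold defaults to 2 mmHg even though 20 mmHg is the
conventional clinical value; it is config-overridable, and under the dose
reading it simply shifts `impair_icp` by a constant (`mean_icp` − 2 for
ICP above threshold), which standardized logistic fits absorb.

A period is excluded (the period, not the patient) when non-missing paired
ABP∧ICP minutes cover less than 50% of its length, or add less than 3 h
over the previous period. Both quantities count data, not elapsed time, so
gaps shorten a period's effective coverage.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
with outcome signal planted only at the latent level:

* Slow vasogenic waves: six sinusoids with random frequencies in
  0.005–0.04 Hz, random phases, standardized; ABP slow SD 4 mmHg around a
  ~85 mmHg baseline, ICP slow SD 2 mmHg around ~12 mmHg.
* Reactivity: each patient has a latent impaired/intact state
  (P(impaired) = 0.8 given unfavourable, 0.2 given favourable, by
  default); the ICP slow wave is \(c\,\hat s_{ABP} + \sqrt{1-c^2}\,\hat
  s_\perp\) with coupling \(c\) drawn around +0.7 (impaired) or −0.5
  (intact), so the pre-noise correlation with the ABP wave equals \(c\)
  exactly. AMP shares the coupling so PAx/RAC/RAP carry the same state.
* Measurement noise at the 10-s scale (SD 1.5/1/2/0.3 mmHg·bpm for
  ABP/ICP/HR/AMP) attenuates realized correlations — planted coupling +0.7
  reads as mean PRx ≈ +0.5, −0.5 as ≈ −0.4 — which is the attenuation the
  test thresholds (> 0.2, < −0.1) anticipate.
* Risk score: class-conditional Beta draws (concentration 8) with class
  means placed symmetrically on the logit scale and the separation solved
  numerically so the between-class AUC equals `crash_auc_target` (0.76).
* Outcome link to ABP: unfavourable patients' ABP baseline is shifted by
  −8 mmHg by default (lower pressure with worse outcome), the second
  planted feature.
* Gaps (2/day, ~15 min, all channels) and artifact spikes (5/day, sized to
  exceed the 6-MAD fence so the repair stage is exercised).
* Waveform mode (default 25 Hz; 250 Hz available) adds ~1.1 Hz cardiac
  pulsation (2.5 mmHg ICP, 40 mmHg ABP pulse pressure) on a spline-smoothed
  upsampling of the 10-s structure. 25 Hz resolves the pulsation for the
  AMP stage at desk-scale cost; decimation does not materially change 10-s
  means. GOS is drawn per outcome class ({1: .65, 2: .05, 3: .30} /
  {4: .4, 5: .6}) so GOS-stratified tables have all five levels.

What the generator does **not** emulate: plateau waves, craniectomy
events, treatment feedback (ICP-directed therapy truncating exactly the
high-ICP excursions that predict outcome), non-stationary reactivity,
beat-to-beat variability, or realistic artifact morphology. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes
from data that contain it — not that comparable effect sizes hold
clinically. Two known emulation artifacts are documented in the tests: the
time-domain AMP reads planted pulsation plus residual slow-structure
traversal (so its mean sits somewhat above the planted 2.5 mmHg), and the
combined model's AUC gain on synthetic cohorts is larger than anything
plausible clinically because the planted two-feature signal is clean.

## Numerical and design choices

* ROC by threshold sweep over unique scores; trapezoid AUC equals the
  tie-adjusted Mann–Whitney statistic identically (tested on random sets
  with forced ties). AUC CI by DeLong placements, normal interval
  truncated to [0, 1]; a degenerate AUC of exactly 0/1 collapses the
  interval with a warning; a patient bootstrap is available as
  cross-check.
* Youden cutoff candidates are midpoints between consecutive unique
  scores plus sentinels beyond both extremes; ties take the lowest cutoff
  (favouring sensitivity). With all scores equal every cutoff has J = 0
  and the rule predicts everyone positive.
* Calibration: 5 equal-width bins on [0, 1] by default; empty bins
  omitted; counts sum to n.
* Windows are left-closed with left-edge timestamps; index windows are
  trailing with their value on the shared 1/min grid, matching bedside
  "updated every minute" semantics.
* ABP zeroing level (heart vs brain) is carried as metadata only; no
  correction is applied, since whether any was applied originally is
  unknown. Risk scores given in percent are detected (values > 1) and
  converted to probabilities on input.
* Everything after cohort generation is deterministic: repeated runs with
  one seed produce byte-identical reports (tested).

## Problem sizes used in the checks

The acceptance-style tests run: 1000 random correlation windows against a
direct Pearson oracle (≤ 1e-12); 100 six-hour patients for PRx sign
recovery; 500 random score sets for the AUC identity; 20 replicate
cohorts of n = 200 (6 h, 10-s resolution) for end-to-end recovery of the
planted ABP + reactivity signal in consensus positions 2–4 and the
combined-vs-baseline AUC gain; one n = 500 null cohort (reactivity link
equalized, ABP effect 0) for the risk-score calibration target 0.76 ±
0.05; and a full double run for byte-identical reproducibility. The
acceptance script itself simulates the study-shaped n = 45, 24-h cohort
and reports per-period out-of-fold AUCs and accuracies.

## Known limitations

* The consensus vote can, in principle, place a parameter whose fold-wise
  positions are bimodal above one that is consistently second; mean-rank
  tie-breaking mitigates but does not remove this.
* The FFS criterion (in-sample AUC) is fit on the same rows it ranks;
  only the outer LOOCV assembly is honest, which is why reported model
  quality uses out-of-fold probabilities only.
* DeLong intervals undercover for AUCs near 1 at n ≈ 45; the bootstrap
  option is the cross-check.
* `segment_ends_hours` beyond the monitored duration are skipped with a
  warning rather than failing, so short-monitoring cohorts degrade
  gracefully.
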