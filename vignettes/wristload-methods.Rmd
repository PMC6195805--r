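---
title: "Methods: accelerometer metrics of running training load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer metrics of running training load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristload)
```

## The measurement model

A wrist-worn triaxial accelerometer sampling at 100 Hz over a ±8 g range
reports, at each instant, the gravity vector plus dynamic acceleration plus
sensor error. `wristload` follows the standard open-source processing
convention:

* **Calibration.** The sensor model is `a_true = offset + scale ⊙ a_raw`
  per axis. During stationary periods the true magnitude is 1 g, so offset
  and scale can be estimated by iteratively regressing the closest points
  on the 1000 mg sphere onto the stationary-window mean vectors
  (`autocalibrate()`). We require ≥ 3 stationary 10-s windows (per-axis SD
  < 13 mg) whose orientations differ pairwise by > 15°; otherwise, or if
  the fit fails to reduce the mean absolute sphere error or produces scales
  outside (0.5, 1.5), an identity calibration is returned with a flag and a
  warning — never a silent failure. The gravity constant is fixed at
  1000 mg exactly (the ENMO convention); no local-gravity correction.
* **ENMO epochs.** Per sample, ENMO = max(0, ‖a‖ − 1000) mg; truncation at
  zero happens per sample *before* averaging into 5-s epochs
  (`compute_enmo_epochs()`). Other orderings (truncate after averaging)
  give different values on oscillating signals; the per-sample convention
  matches the published ENMO definition. Epochs are aligned to the time
  origin (midnight for seconds-of-day timestamps); partial first/last
  epochs are dropped, not padded.
* **Non-wear.** The source protocol filters days by wear hours but does
  not state a non-wear algorithm, so we adopt the processing chain's
  published heuristic: 60-min windows evaluated every 15 min; a window with
  per-axis SD < 13 mg and range < 50 mg on ≥ 2 axes marks its epochs
  non-wear (`detect_nonwear()`). All thresholds are arguments. A
  consequence worth knowing: a perfectly noise-free signal confined to one
  axis has two flat axes and is flagged non-wear; real sensors always carry
  noise on all axes.
* **Valid days.** Days with strictly less than 10 h of wear are excluded
  (`filter_valid_days()`). The waking-day operationalisation is uncited
  detail in the source protocol; the default counts the full 24-h day, and
  a waking window (e.g. 06:00–24:00) is available via `waking_window`.

## Daily metrics

All metrics are computed from wear epochs of one calendar day
(midnight-to-midnight, no wraparound):

| metric | definition | units |
|---|---|---|
| `avg_accel` | mean epoch ENMO over wear epochs | mg |
| `most_active_30` | max mean over contiguous all-wear 360-epoch windows, stride 1 | mg |
| `mins_ge_400` | wear epochs with value ≥ 400 mg × 5/60 (inclusive boundary, as the name says) | min |
| `bin_minutes` | wear epochs assigned to half-open 50-mg bins [50,100) … [3950,4000), plus an overflow bin ≥ 4000; values < 50 mg are non-meaningful and uncounted | min |
| `wl_400_4000` | Σ over bins with lower edge in [400, 4000) of representative intensity × bin minutes; overflow excluded (time above 4000 mg is extremely brief and rare) | mg·min |

Choices the field leaves open, and what we picked:

* The most-active window is contiguous, stride one epoch, wear-only, no
  midnight wraparound. A stride was not stated in the source description
  ("most active continuous 30 min"); stride 1 is the natural reading.
* Bin membership uses half-open intervals, matching "50–99.99 mg"
  phrasing, applied to epoch means (not raw samples).
* The workload representative intensity is the bin midpoint by default;
  "intensity multiplied by duration" does not fix the representative, so
  lower- and upper-edge variants are exposed (`wl_representative`).
* 400 mg is a published vigorous-intensity threshold for adult wrist
  accelerometry; running at 8 km/h yields ≈ 760 ± 200 mg and fast walking
  ≈ 170 ± 56 mg, so 400 mg leaves margin on both sides.

## Day labelling and training load

Training-log sessions carry date, start/end clock times (duration derived),
activity type, running miles and a 1–10 session RPE. Any running session
(road, off-road, track or treadmill) makes the day a *running* day; a day
with sessions but no running is *other training*; a monitored day with no
entries is *rest*. For multi-run days, miles and running duration are
summed, a mean running RPE is computed, and the session-RPE training load
is recalculated as mean RPE × summed duration (arbitrary units).
Non-running sessions never feed the three running criteria (miles,
duration, training load); how they should is not specified anywhere, so
they are excluded and only their labels are kept for the misclassification
breakdown. Overnight sessions are rejected rather than wrapped.

## Classification

For each metric, the empirical ROC over all distinct observed values
(classify running iff value ≥ threshold) gives the AUC as the Mann–Whitney
statistic with ties credited ½ — identical to the trapezoidal area.
"Optimising the balance between sensitivity and specificity" is
implemented as Youden's J with ties broken by minimal |sens − spec|; the
reported cutpoint is the midpoint between the optimal observed value and
the adjacent lower one, which places the boundary between classes instead
of on a data point. Closest-to-(0,1) selection is available
(`rule = "closest_topleft"`); the two rules can disagree and nothing in the
source adjudicates, so the rule is a config key recorded in provenance.

Cross-validation leaves out one *participant* per fold by default — days
cluster within runner, and per-day leave-one-out would leak that cluster
structure — with per-day folds available (`cv_unit = "day"`). Held-out AUC
is computed only for folds containing both classes; pooled held-out
accuracy uses every fold. The AUROC sample-size computation uses the
Hanley–McNeil negative-exponential approximation (Q1 = θ/(2−θ),
Q2 = 2θ²/(1+θ), kernel V = Q1 + Q2 − 2θ², equal groups, two-sided α) with
ceiling rounding per group; with an alternative of 0.6 against 0.5 it
returns 129 per group / 258 total, which is the design figure this
approximation was chosen to reproduce.

## Convergent validity

On days *classified* as running by each high-accuracy metric cutpoint —
deliberately including misclassified days, whose logged criteria are
legitimately zero — ordinary least squares regresses each criterion on
each predictor (simple OLS, not mixed-effects, matching the source
analysis; clustering is handled only through the fold structure). The
cross-validated statistic is predicted R² in pooled-PRESS form,
`1 − Σ(y − ŷ_heldout)² / Σ(y − ȳ)²`; the source does not define its CV
statistic, and pooled PRESS is the standard choice. It can be negative on
uninformative cells. Unadjusted R² is reported by default ("variance
explained"); adjusted R² is a flag. A secondary analysis on log-labelled
running days is appended as classifier `training_log`.

## The synthetic cohort: what it emulates, and what it does not

No real data ship with the package, so `generate_cohort()` produces the
world the analysis assumes: ~35 runners monitored in 7-day blocks on
alternate weeks (~43 days each), each day running / rest / other-training
with probabilities 694:641:159 (≈ 0.465/0.429/0.106), cross-training split
roughly 30% cycling, 28% gym, 13% circuits, 11% field/racket, 10% swim,
8% other. About 2.5% of days carry an 18-h non-wear bout and fail the 10-h
filter (emulating ~97.5% retention), and 5% carry a short early-morning
bout.

Intensity profiles (5-s epoch mean ± SD, mg) anchor on published wrist
calibration values for running (760 ± 200) and walking (170 ± 56). The
remaining profiles — cycling 450 ± 250, gym 300 ± 180, circuits 420 ± 200,
field/racket 600 ± 250, swim 200 ± 100, sedentary 30 ± 25, sleep 10 ± 10 —
are *calibrated assumptions*: no published epoch distributions exist for
these activities at the wrist, and the defaults were chosen once so that
the generator reproduces the qualitative misclassification regime reported
in the field (field/racket sports confused with running far more often
than gym work; cycling and circuits in between; swimming essentially
never) and then frozen. They are configurable and must not be read as
ground truth.

Other stated-world choices, also fixed once:

* Days run midnight-to-midnight; sessions sit between 06:00 and 21:00;
  sleep background before 06:30 and after 22:30, sedentary otherwise.
* Running session durations ~ Normal(50, 15) min clamped to [20, 120];
  10% of running days hold two runs. Cross-training sessions
  ~ Normal(45, 15) min clamped to [20, 90].
* True miles = duration / pace with per-participant pace uniform on 9–11
  min/mile, and running intensity scales with pace (profile mean ×
  10/pace): faster runners hit higher wrist accelerations. Each session
  additionally shifts its profile mean by Normal(0, 0.3 × SD) — doubled
  for cross-training, whose day-to-day intensity varies more than habitual
  running. This heterogeneity is what separates the minutes-based and
  workload-based predictors in the validity analysis; with none, the two
  would be collinear.
* Session RPE ≈ 1 + duration/15 + intensity noise, rounded and clamped to
  1–10, so training load correlates with duration by construction.
* Epoch values are Normal draws truncated at 0. Raw 100 Hz synthesis
  (gravity along a fixed orientation plus a non-negative oscillation with
  an integer number of cycles per epoch, so the per-epoch mean is exact)
  is reserved for signal-processing tests; generating 8.64 M samples per
  day for whole cohorts buys nothing.
* Log noise (entry omission, miles error, RPE jitter) defaults to zero —
  the emulated logs were exhaustive — and is available to study
  self-report error.

What a green end-to-end test therefore establishes: the pipeline's
machinery (metrics, cutpoints, cross-validation, regressions) behaves
correctly and reproduces the *qualitative* structure of the published
analysis on data built to its assumptions. What it does not establish:
the published cohort's numerical cutpoints or R² values (that cohort's raw
data are not available), robustness to real-world artefacts (device swaps
between wrists, temperature drift, idle-sleep modes, irregular sampling),
or the realism of the invented cross-training profiles.

## Numerical conventions and degenerate inputs

* Zero wear epochs → metrics are `NA` (undefined), never zero.
* Classification is inclusive: value = cutpoint ⇒ running; an epoch at
  exactly 400 mg counts; an epoch at exactly 4000 mg is overflow.
* Uninformative ROC data (J ≤ 0 everywhere) yields a cutpoint with a
  warning and an `uninformative` flag.
* Single-class inputs error in `roc_curve()`; single-class *training*
  folds are skipped with a warning; degenerate cohorts abort the pipeline
  with a stage-named error.
* Seeds: one integer drives the whole study; all generators draw from the
  global RNG after `set.seed(seed)`, making every output byte-identical
  across runs.
* Configs are JSON (not YAML): the package avoids adding a YAML dependency
  since its entire schema is flat key-value data that JSON covers.

## Known limitations

* The non-wear heuristic and waking-day definition are assumptions where
  the source protocol is silent; both are configurable, and the retention
  fraction is reported so their effect is auditable.
* Per-activity misclassification uses day-level activity presence; a day
  with two different cross-training sessions counts toward both
  activities.
* The workload monotonicity property (raising an epoch never lowers a
  metric) has one documented exception: an epoch crossing 4000 mg moves
  into the excluded overflow bin. At physiological intensities this does
  not occur.
* `fnv1a` provenance hashes are for change detection, not integrity.
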