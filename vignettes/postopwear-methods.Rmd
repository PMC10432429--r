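---
title: "Methods: wearable-based early detection of abnormal postoperative recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-based early detection of abnormal postoperative recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After an appendectomy, children are discharged home and their caregivers
must judge recovery from subjective cues. Abnormal recovery — an abnormal
symptom (fever, vomiting, incisional redness) or a confirmed complication
(surgical-site infection, intraabdominal abscess, bowel obstruction) —
often announces itself in behavior before it is reported: activity drops,
heart rate rises, sleep is disturbed. A wrist-worn consumer device records
all three continuously. `postopwear` implements the full analysis chain for
asking a precise question of such data: *can a day-level classifier flag
the one to two days preceding a reported postoperative event, early enough
for a clinician to intervene?*

Because real postoperative wearable datasets are access-restricted, the
package is built around a synthetic cohort generator that reproduces the
statistical shape of a 21-day post-appendectomy monitoring study: two
severity groups (complicated appendicitis, with perforation/phlegmon/
abscess at surgery, and simple appendicitis), minute-level heart-rate and
step streams with realistic non-wear gaps, daily activity/sleep summaries,
and sparse dated events graded on the Clavien-Dindo scale. Every
downstream stage — feature engineering, labeling, model fitting,
evaluation — is exercised and tested against this generator, and accepts
user-supplied CSVs in the same documented dialect.

## Day indexing and ground truth

POD 0 is the day of surgery; monitoring covers POD 1..21. For an event
reported on POD $k$:

* PODs $k-2$ and $k-1$ (those that exist and are $\ge 1$) are labeled
  **abnormal**;
* POD $k$ itself is **excluded** from training and testing — the goal is
  detection *before* the report, and the event day would leak the outcome;
* all remaining days are **normal**.

An event on POD 2 therefore contributes one abnormal day, an event on
POD 1 none. When rules collide the precedence is excluded > abnormal >
normal: a day that is simultaneously an event day and inside another
event's pre-event window stays excluded, because event days are
unconditionally unusable. Days after an event revert to normal unless a
later event's window captures them. Each event owns its own window even
when windows overlap, which matters for the event-level denominators
below. The labeling is verified in the test suite against an exhaustive
rule interpreter over every event configuration of up to four events in a
21-day window.

Both symptoms and confirmed complications are "postoperative events" and
label identically; the distinction (an event is a complication iff it is
on the NSQIP list) is carried through as a clinical feature and in the
missed-event reporting, not in the labels.

## Features

Each patient-day with any recorded data becomes one row of 74 features:

* **Activity (14)** and **sleep (4)** daily-summary fields are passed
  through as recorded (steps, distances by intensity, intensity minutes,
  calories, minutes asleep/in bed/restless, sleep-period count). These are
  vendor-computed quantities; the package never re-derives them from raw
  signals.
* **Heart rate (5)**: resting heart rate from the daily summary, plus
  mean, SD, min, max over the day's *worn* minutes. A minute counts as
  worn iff its heart-rate sample is present and positive. The SD uses the
  sample ($n-1$) denominator; one worn minute leaves the SD missing, zero
  worn minutes leave all four missing — never zero, which would fabricate
  a physiological value.
* **Temporal variants (35)**: for seven flagged features (total steps,
  total distance, calories, resting HR, minutes asleep, minutes in bed,
  minutes restless), five change measures: difference from the previous
  day, difference from and percent change against the 3-day rolling mean,
  and difference from the running maximum and minimum of all previous
  days. The rolling window is the three preceding *calendar* PODs with
  missing days skipped, and excludes the current day — a variant that
  included the current day would partially encode the value it is supposed
  to contrast with. Any variant without qualifying prior data is missing;
  missingness is a value, not an error.
* **Demographics (8)**: age, weight, height, a male indicator, and
  race/ethnicity one-hot in four columns.
* **Clinical (8)**: days since surgery, days since the last prior symptom
  and complication, past-event booleans and cumulative counts (events
  strictly before the day), and a discharge indicator
  (`pod >= ceiling(length_of_stay)`). When no prior event of a category
  exists, the days-since features fall back to days since surgery — an
  upper bound that keeps the feature numeric without a sentinel constant.

36 named base quantities with race expanded to four indicators give 39
base columns; adding $7 \times 5$ variants gives the canonical 74. The
source study counts 75 features for an equivalent table; the enumeration
there is not fully recoverable, and this package fixes the canonical set
at 74 rather than invent a column.

Wear time is computed per day as worn minutes inside the potential waking
window 06:00–24:00, divided by 60 (so at most 18 h). The compliance filter
used by the wear-time sensitivity analysis keeps days with $\ge 10$ h.

## The classifier

Abnormal days are rare (a few percent), so an ordinary forest would learn
to say "normal". The package uses a **balanced random forest**: each of
100 trees is grown on a bootstrap that draws $n_{\text{minority}}$ rows
with replacement from *each* class — exact class balance per tree —
with $\lfloor\sqrt{p}\rfloor$ candidate features per split, trees grown to
purity, and Gini (impurity) importance recorded. A day's score is the
fraction of trees voting abnormal; the predicted label is abnormal at
score $\ge 0.5$, with the tie deliberately counted as abnormal since in
this application a false alarm costs a phone call and a miss can cost a
readmission. Tree induction is delegated to `ranger` with class-wise
resampling fractions, which realizes exactly this balanced bootstrap; the
test suite verifies per-tree inbag class counts.

Hyperparameters (100 trees, unlimited depth, $\sqrt p$ mtry, 0.5 vote
threshold) are standard balanced-random-forest practice; all are
overridable in `model_params()`.

Two preprocessing steps precede each fit:

* **Correlation pruning**: a greedy scan in canonical column order drops a
  feature whose absolute pairwise-complete Pearson correlation with any
  already-retained feature exceeds 0.95. Greedy-in-fixed-order makes the
  result deterministic; zero-variance features (undefined correlation) are
  retained and flagged.
* **Imputation**: each missing cell is filled with that patient's mean of
  the feature over their included days; a patient with no observation of a
  feature falls back to the training-split grand mean.

Evaluation is by **leave-one-subject-out cross-validation**: one fold per
patient, the model trained on all other patients and scored on every
included day of the held-out patient. Days of one child are strongly
dependent, so a day-level split would leak identity; subject-level
holdout is the honest unit. By default pruning and imputation are re-fit
inside each fold from training patients only, so nothing about the
held-out patient influences preprocessing. Because the source analysis
describes a single preprocessing pass, `model_params(paper_faithful =
TRUE)` instead fits both once, globally; which of the two the original
analysis used is not stated, so both are provided and neither asserted.
Separate models are fit for the complicated and simple groups — their
recovery trajectories differ too much to pool by default; pooling is
sensitivity analysis 4.

## Evaluation

Per-fold metrics are frequently undefined with a single held-out patient
(often one class), so day-level metrics are computed on the **pooled**
out-of-fold scores: confusion matrix and percent of normal/abnormal days
correct, AUROC (midrank Mann–Whitney form, exactly the pairwise
concordance probability with ties at ½), and AUPRC as interpolation-free
average precision, alongside its prevalence baseline
$n_{\text{abnormal}}/n_{\text{days}}$ — the expected AUPRC of a random
scorer, the right yardstick for a rare-event detector. 90% confidence
intervals come from a patient-level percentile bootstrap (patients
resampled with replacement, their days pooled; 1000 reps by default,
seeded), which respects within-patient correlation; the interval method
was not specified in the source study, so this choice is the package's
own. Degenerate single-class resamples are skipped, and the interval is
reported missing if they exceed half the draws.

Event-level early detection asks, per event on POD $k$: was POD $k-2$
(**d−2**) or POD $k-1$ (**d−1**) predicted abnormal, counting only days
present in the modeling table? **d_ANY** is detection on either day. The
d−2 denominator excludes events on POD ≤ 2 and the d−1 denominator events
on POD 1, since those prior days do not exist after surgery; an event with
no existing labeled prior day at all (e.g. a POD-1 event, or both prior
days devoid of data) leaves every denominator. The alternative — counting
such events as undetected — is arguable from the source study's summary
phrasing; exclusion was chosen because a detector cannot be charged with
missing a day that does not exist, and the denominators are always
reported alongside the percentages. Events in the d_ANY denominator that
are detected on neither day are listed with their Clavien-Dindo grade.

Gini importances are averaged across folds (a feature pruned in a fold
contributes zero there), normalized to sum to one, and ranked.

Four sensitivity analyses re-run the entire LOSO pipeline: (1) clinical +
demographic features only (no wearable data), (2) only days with ≥ 10 h
waking-window wear, (3) one device generation at a time, (4) both severity
groups pooled.

## The synthetic cohort generator

The generator's defaults are the study conditions the analysis assumes:

* 85 complicated + 76 simple patients; ages $\mathcal N(10.4, 3.6^2)$
  truncated to [3,17]; sex and race/ethnicity drawn at the study's
  frequencies; length of stay $\mathcal N(4.0, 2.6^2)$ (complicated) and
  $\mathcal N(0.9, 0.7^2)$ (simple), floored at 0.2 days; devices
  Inspire HR with probability 69/85 and 43/76 per group.
* Events per patient are Poisson with group rates 41/85 and 10/76, days
  uniform over POD 1..21 without replacement; grades drawn at the study's
  frequencies (22/14/5 for I/II/III complicated, 9/0/1 simple), NSQIP
  status by grade (never for I, mostly for II's listed examples, always
  for III).
* Daily expected steps follow a logistic recovery ramp from a nadir (20%
  of an age-scaled plateau, 10 000 steps/day at age 10) toward the
  plateau, with midpoint POD 10 (complicated) vs POD 4 (simple) and
  log-normal day-to-day noise (sdlog 0.25). Steps are spread over worn
  minutes by zero-inflated gamma weights, giving a realistic mix of
  sedentary and active minutes; minute heart rate is a patient baseline
  declining with age, plus a day effect, a step-rate term, and noise.
* Daily wear hours are Normal(12.8, 6.0) (complicated) / Normal(12.3,
  6.3) (simple) censored to [0, 18], realized as a contiguous worn block
  inside 06:00–24:00; a day censored to zero wear produces no minutes and
  no daily summary — a no-data day. 15% of worn days record no sleep.
* On the 1–2 days before each event, minute steps are scaled by
  $1 - s$ and minute heart rate is raised by $e$ bpm. The study reports no
  effect size for this pre-event physiology, so $(s, e)$ is a free
  parameter; the package default $(0.5, 15)$ is its canonical
  strong-signal demonstration. A day inside two events' windows is
  perturbed once.

Event *timing* is uniform over the window by design: with timing
uninformative, clinical features (days post surgery, past events) carry no
systematic label signal under a homogeneous event process, so any
discrimination the model finds must come from the injected wearable
perturbation. This makes the package's null and ablation checks
meaningful: with the effect set to zero the pooled LOSO AUROC must sit at
chance, and removing wearable features from a strong-signal cohort must
not improve AUROC. It is also the generator's main departure from the
clinical reality that events cluster early in recovery — as do several
others: heart-rate dynamics are not physiologically validated, there is no
circadian structure beyond the wear window, sleep is independent of
activity, and reporting behavior (recall bias, phone-survey cadence) is
not modeled. Passing tests on this generator therefore demonstrate that
the pipeline recovers a known signal under realistic sparsity, imbalance,
and missingness — not that a given AUROC would be attained on clinical
data.

## Numerical choices and degenerate inputs

* Determinism: every stochastic step (generation, bootstraps, tree
  growing, CI resampling) is seeded; fold seeds derive from the base seed,
  and `ranger` runs single-threaded, so identical seeds give bit-identical
  cohorts, scores, and reports.
* `train_brf()` refuses to fit with fewer than two abnormal training days;
  `loso_cv()` requires two patients; `run_group_analysis()` skips a group
  whose assembled dataset is degenerate (one class or < 2 abnormal days)
  with a message rather than an error, so one degenerate group does not
  abort a multi-group run.
* AUROC/AUPRC with a single class present are missing, not 0 or 0.5.
* A feature with no observed value in a training split is dropped with a
  warning before pruning.
* Duplicate event records (same patient, day, category) collapse with a
  warning; recurrences of the same symptom on different days are distinct
  events, each generating its own window.

## Problem sizes used in the tests

The packaged test-suite runs the full study-scale configuration
(85 + 76 patients) once for the strong-signal and ablation checks and ten
times at zero effect size for the null check; property-style suites use
small randomized instances (≤ 12 days for the exhaustive AUROC oracle,
≤ 4 events for the exhaustive labeling oracle, as those bounds keep the
brute-force oracles exact and fast). Single-run LOSO AUROC has an
analytic standard error of roughly 0.035 at this class balance, so the
null check constrains the mean over ten seeds to [0.4, 0.6] with a wide
3σ per-seed band.

## Known limitations

* The generator is a statistical stand-in, not a physiological simulator;
  see above for what it does not emulate.
* The classifier seam is fixed to the balanced random forest; alternative
  imbalanced-learning ensembles can be swapped in only by replacing
  `train_brf()`/`predict.brf_model()`.
* Severity-aware labeling is deliberately out of scope: all events,
  Grade I through III, label identically.
* Real-data ingestion expects the documented CSV dialect; arbitrary
  vendor exports need reshaping first.
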