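---
title: "Grading facial nerve function from bilateral surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading facial nerve function from bilateral surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After vestibular schwannoma surgery, facial nerve function is routinely
scored on the House–Brackmann (HB) scale, an ordinal clinical rating from 1
(normal) to 6 (total paralysis). The rating is quick but subjective, with
well-documented interobserver variability. Surface EMG (sEMG) of the mimic
muscles offers an objective alternative: a paretic hemiface produces weaker
voluntary activity than the healthy side, and that asymmetry grows with the
degree of palsy.

`semgrade` implements a semi-automated grading pipeline built on exactly this
idea. Three muscles — orbicularis oculi, nasalis, orbicularis oris — are
recorded bilaterally while the patient performs seven standardized facial
poses, three brief tension–relaxation repetitions each (roughly 1 s tension,
3 s relaxation). The pipeline reduces each recording session to 21
asymmetry features and classifies the HB grade with simple, untuned machine
learning models under leave-one-patient-out cross-validation.

## From raw trace to one amplitude

Each trace passes through four steps (`process_traces()`):

1. **Rectification** — absolute value of every sample (`rectify()`).
2. **Smoothing** — centered 100 ms running average
   (`smooth_running_average()`). Windows are truncated at the trace edges
   (the mean runs over the samples actually available), so a constant trace
   maps to itself and no zero-padding bias is introduced. The window length
   in samples is `round(window_ms * fs / 1000)`, minimum 1; for an even
   window the extra sample sits right of center.
3. **Epoch selection** — the 500 ms window with the largest mean of the
   smoothed rectified signal (`select_epoch()`), ties broken toward the
   earliest start. In the original manual workflow an examiner picked the
   epoch containing the movement's maximum amplitudes by eye; the automated
   search needs the envelope first, which is why rectification and smoothing
   precede selection here. Manually chosen epochs can still be supplied via
   `manual_epochs` and take precedence.
4. **Amplitude** — the 95th percentile of the smoothed rectified samples in
   the epoch (`amplitude_95()`), a robust stand-in for the peak. The
   percentile uses linear interpolation between order statistics (type-7
   quantile); the estimator is fixed so results are reproducible.

The chain is invariant to a sign flip of the raw signal and scales linearly
with the input, both enforced by tests.

## Lateralization indices

Absolute sEMG amplitudes vary strongly with skin impedance, electrode
placement and anatomy. The feature used for grading is therefore the
within-patient asymmetry, the lateralization index

\[
\mathrm{LI} \;=\; \frac{\mathrm{EMG}_{\mathrm{ipsi}} - \mathrm{EMG}_{\mathrm{contra}}}
                      {\mathrm{EMG}_{\mathrm{ipsi}} + \mathrm{EMG}_{\mathrm{contra}}}
\in [-1, 1],
\]

where *ipsi* is the side of the operated (tumor) hemiface. LI = 1 means
activity only on the operated side, LI = −1 only contralateral, 0 perfect
symmetry; a paretic operated side drives LI negative. The degenerate case
0/0 is defined as 0 (no lateralization information). LI is computed per
muscle × pose × repetition and averaged over the available repetitions,
giving 3 × 7 = 21 features per measurement (`build_features()`). Averaging
repetitions rather than concatenating them was a deliberate choice: it is
the most compact representation consistent with computing LI per repetition,
and the repetition count per feature vector stays fixed even when a
repetition is missing. Absolute amplitudes are deliberately not used as
features.

Two imputation rules handle incomplete sessions, mirroring how missing
movements are handled clinically:

* a pose with at least one usable repetition keeps the mean of what is
  there (`partial_repetitions` flag);
* a pose with no usable repetition receives the mean LI of that muscle's
  other poses (`whole_movement` flag) — per muscle, because LI scales differ
  across muscles. A repetition with only one side recorded is dropped (an
  LI needs the pair).

Imputation never leaves the observed range of the muscle, and side-swap
antisymmetry and amplitude-scale invariance of the full feature map are
enforced by tests.

## Classification design

Three clinically motivated scenarios (`scenario_spec()`):

1. **HB 1 vs HB 2–6** — normal vs any impairment (binary),
2. **HB 1–2 vs HB 3–6** — no or slight vs moderate-or-worse impairment
   (binary); clinically the most relevant cut, since HB 3 marks incomplete
   eye closure,
3. **HB 1 / 2 / 3** — three-class; grades 4–6 are excluded because they are
   far too rare for per-grade classification.

Three classifiers with fixed, untuned hyperparameters (`classifier_spec()`):
logistic regression, an RBF-kernel SVM with `gamma = 1/n_features` and
`C = 1`, and 5-nearest-neighbours with inverse-distance neighbour weights.
Small-sample choices that the design left open were resolved as follows and
are part of the package contract:

* **Logistic regression** uses ridge regularization (`glmnet`, `alpha = 0`,
  `lambda = 1/n_train`, i.e. the classical unit-cost penalty), multinomial
  for scenario 3. With 21 features and ~55 training cases an unpenalized fit
  would separate perfectly and return degenerate probabilities.
* **SVM probabilities** come from Platt-style sigmoid calibration fit on the
  training fold (`kernlab::ksvm`, `prob.model = TRUE`). On folds too small
  for the internal calibration split, the model falls back to hard
  (one-hot) class assignments — only reachable in miniature test cohorts.
* **KNN** weights the 5 nearest training points by 1/distance, normalized;
  an exact match (distance 0) takes all the weight.
* **Standardization**: features are centered and scaled with statistics of
  the training fold only (constant features get scale 1). This is required
  for sensible distance and kernel behavior and can be disabled
  (`standardize = FALSE`).
* **Tie-break**: predicted class = argmax probability, ties resolving toward
  the better (lower) grade — deterministic, and consistent with reporting an
  underestimation tendency honestly.

**Cross-validation** is leave-one-*patient*-out (`loo_cross_validate()`):
every fold holds out all measurements of one patient, so a patient's preop
session can never inform the grading of their own postop session. Test-fold
class probabilities are accumulated over folds and all metrics are computed
on that accumulation: rank-based (Mann–Whitney) ROC-AUC for the binary
scenarios, one-vs-one multiclass AUC (mean over class pairs of the mean of
the two directed pairwise AUCs) for scenario 3, plus the ordinal breakdown
into concordant / underestimated ("better" than clinical) / overestimated
predictions. AUC is preferred over accuracy because the grade distribution
is heavily imbalanced. Since an aggregate of three per-classifier AUCs can
be read as either mean or median, the per-scenario summary reports both,
labeled explicitly (`glance()`).

A single seed (argument `seed`) governs every stochastic component — in the
default configuration that is only the SVM calibration split — so a rerun of
`run_pipeline()` with the same configuration reproduces every artifact byte
for byte.

## The synthetic cohort generator

No clinical recordings ship with the package; `simulate_cohort()` generates
cohorts whose structure mirrors the perioperative study design, so every
stage is testable end to end. The default configuration reproduces the
reference cohort composition exactly: 59 measurements over 28 patients
(most contributing a preop and a postop session, three patients a follow-up
as well), with clinical labels 30 × HB 1, 17 × HB 2, 5 × HB 3, 3 × HB 4,
2 × HB 5 and two measurements whose clinical grade is missing (truth grades
HB 1 preop / HB 2 postop). Assigned grades are shuffled over session slots;
the operated side is fixed per patient.

The waveform model is deliberately the simplest process with realistic
envelope statistics: unit-variance band-limited Gaussian noise (4th-order
Butterworth band-pass, 20 Hz to min(450, 0.45 fs) Hz) multiplied by

\[
\sigma(t) = \texttt{baseline\_noise\_uv} + A \cdot \mathrm{trapezoid}(t),
\]

a trapezoidal tension envelope (10% rise/fall of the 1 s tension time) with
its onset jittered uniformly within the 4 s trace. The 95th-percentile
envelope amplitude is then proportional to σ in the tension window, so
attenuating the burst drive propagates monotonically into LI.

The grade acts through the ipsilateral drive multiplier
`grade_attenuation = (1, 0.75, 0.5, 0.3, 0.15, 0)` for HB 1–6 — an invented,
configurable mapping chosen once to make grades separable while keeping
neighbours close; it is not calibrated against clinical data. Three
additional mechanisms give the cohort realistic overlap between adjacent low
grades:

* `repetition_cv = 0.15` — lognormal amplitude jitter across the three
  repetitions (voluntary effort varies);
* `subject_asymmetry_cv = 0.2` — a lognormal ipsi/contra gain mismatch drawn
  per session and muscle, standing in for anatomical asymmetry and
  electrode-placement differences. This is the reason HB 1 vs HB 2 is
  genuinely hard (both hover near |LI| ≈ 0.1) while HB 3+ remains
  separable — the same qualitative pattern that makes the slight-vs-moderate
  cut the easiest scenario;
* `synkinesis_gain = 0.05` — a fraction of each side's drive leaking to the
  other side, the simulator's nod to synkinetic co-activation.

These defaults were fixed a priori as the package's study conditions and are
exercised as such by the test suite; they are arguments, not constants.
Dropout rules (`dropout_spec()`) emulate patients who cannot perform a
movement: a pose missing entirely, or accomplished once instead of three
times — the two cases the imputation rules exist for.

What the generator does **not** emulate: motor-unit physiology, fatigue,
electrode geometry, cross-talk between muscles beyond the single synkinesis
gain, non-stationary baselines, movement artifacts, or any correlation
between timepoint and grade within a patient's trajectory. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's mechanics are
correct and that grade-driven asymmetry of the assumed form is recovered;
they say nothing about classification performance on clinical recordings.

## Problem sizes and numerical conventions

The test suite checks the signal operations against brute-force oracles
(direct windowed means, exhaustive epoch scans, pairwise Mann–Whitney
enumeration — 1000 random binary instances with n ≤ 50, plus pairwise
enumeration for the one-vs-one AUC), and runs the full default cohort
(59 sessions at 1000 Hz, ~30 M samples) end to end once, asserting the
recovery pattern: scenario-2 AUC ≥ 0.9 for at least one classifier,
scenario-1 AUC above chance for all three, and scenario 2 ahead of
scenario 1 on average. Unit tests use miniature cohorts at 200 Hz with
shortened traces; those sizes are chosen so the whole suite stays fast while
every code path — including dropouts, missing labels and degenerate folds —
is exercised.

Conventions worth knowing when comparing against other implementations:
type-7 percentile; truncated (not zero-padded) smoothing windows; epoch
ties to the earliest start; LI 0/0 = 0; probability ties to the better
grade; AUC ties count 1/2. `scripts/acceptance.R` re-runs the default
pipeline from scratch and writes every headline number (per
scenario × classifier AUC, concordance breakdown, cohort composition) as
JSON.

## Limitations

* The generator's grade–attenuation mapping is a modeling convenience;
  absolute AUC values on synthetic cohorts are optimistic relative to
  clinical data and should be read only qualitatively.
* Grade assignment ignores within-patient disease trajectories (a patient
  may draw HB 1 postop and HB 3 preop); grouped cross-validation is
  unaffected, but longitudinal analyses would need a trajectory model.
* EDF input is not supported; recorded data enter through the long-format
  CSV dialect documented in `write_cohort_csv()`.
* The ordinal structure of the HB scale is not exploited by the classifiers
  (multinomial, not ordinal, regression in scenario 3) — by design, to keep
  the classifier set minimal and untuned.
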