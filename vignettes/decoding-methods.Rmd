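---
title: "Time-resolved decoding of oddball ERPs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of oddball ERPs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erpmvpa)
```

## The problem

In an auditory oddball paradigm, a stream of frequent "standard" tones is
interrupted by rare "deviant" tones (here, duration deviants). The brain's
automatic change-detection response produces a mismatch negativity (MMN), a
frontocentral negative deflection roughly 100–250 ms after the deviant, often
followed by a P3a positivity around 250–350 ms. In comatose patients these
responses can appear and disappear over the course of hours — they wax and
wane — so a single grand average over a long recording can miss a transiently
present response.

`erpmvpa` treats the question "does this recording contain a discriminable
deviant response, and when?" as a single-subject classification problem: at
every post-stimulus time point, a linear support-vector machine is trained to
separate standard from deviant trials using the electrode amplitudes at that
time point as features, and its held-out performance is summarized as the
area under the ROC curve (AUC). 0.5 is chance; 1.0 is perfect separation.

## The decoding procedure

For one dataset (a "superblock" of concatenated recording blocks, or a single
block), the pipeline is:

1. **Undersampling.** Oddball designs are unbalanced by construction.
   Majority-class (standard) trials are randomly removed until the classes
   are equal, once, before any cross-validation split.
2. **Repeated stratified cross-validation.** `n_folds = 5` outer folds,
   repeated `n_repetitions = 10` times with fresh fold assignments. The
   reported dispersion is the standard deviation over the 50 fold-by-
   repetition AUC estimates — the only dispersion the procedure produces.
3. **Nested z-scoring.** Per feature (channel at a time point), the mean and
   sample standard deviation (n − 1) of the *training* trials standardize
   both training and test data. Test data never contribute to the statistics.
   A zero-variance training feature is centered but left unscaled, with a
   warning, so that noiseless fixtures remain analyzable.
4. **Nested pseudo-trial averaging.** Within the training partition, trials
   of each class are randomly split into groups of exactly `k` and replaced
   by the group means (`k = 5` for superblocks, `k = 2` for single blocks;
   remainder trials are dropped). Test trials are grouped independently
   within the test fold. Averaging k i.i.d. trials reduces noise variance by
   1/k while leaving the signal mean untouched, trading observations for
   signal-to-noise ratio. Groups are re-drawn at every fold and repetition —
   this is the randomness the repetitions average over.
5. **Linear SVM with inner-CV cost selection.** Cost candidates span
   0.01–100 in 7 log-spaced steps. Within each outer training fold, an inner
   3-fold cross-validation scores each candidate by its mean AUC over ~12
   evenly spaced time points, and the winner (ties to the smallest C) is
   used for every time point of that fold. Selecting per fold rather than
   per time point keeps the cost of the permutation machinery proportionate;
   for z-scored ERP features the AUC of a linear SVM is largely insensitive
   to C, and the selection is still strictly nested (it sees training data
   only — verified by a leakage probe in the test suite).
6. **Scoring.** Held-out pseudo-trials are scored by the signed distance to
   the hyperplane, oriented so larger scores favor the class named
   `"deviant"`, and summarized by the rank-based AUC (ties count one half).

Because score orientation follows the *name* of the deviant class, renaming
the two classes leaves the decoding curve exactly invariant (the hyperplane
is label-symmetric; negating the scores and swapping the positive set
cancel). The familiar 1 − AUC antisymmetry lives at the metric level:
`auc(pos, neg) = 1 - auc(neg, pos)` exactly.

### The classifier engine

The hot loop fits one SVM per time point, fold, repetition, permutation and
searchlight cell — easily 10^5–10^6 fits per analysis. The package therefore
ships a compiled dual coordinate-descent solver for the L2-regularized
hinge-loss linear SVM (the liblinear algorithm, with the bias as an
augmented regularized feature; deterministic fixed-order sweeps, stopping
tolerance 1e-4 on the projected gradient). Since the AUC only depends on the
ordering of decision values, the bias convention is immaterial to every
reported number. `decoding_config(engine = "libsvm")` switches to
`e1071::svm` (libsvm). The two bias conventions yield identical solutions
only when the optimal bias is near zero — which the pipeline's nested
z-scoring guarantees — and the test suite cross-checks the engines there,
both at the weight-vector level on centered problems and at the
decoding-curve level on shared pipeline fixtures.

### Temporal generalization and searchlight

The temporal generalization matrix trains the per-time-point classifiers
exactly as above (same folds, groups and selected cost for the same seed)
and evaluates each on every other time point, so its diagonal reproduces the
time-resolved curve to within 1e-12 (tested). Off-diagonal structure
indicates representations shared across latencies.

The searchlight repeats the cross-validated classification with features
restricted to a single channel's samples within one window — the baseline
(−100..0 ms) plus ten 50 ms bins from 50 to 550 ms — mapping where the
discriminative information lies. Single-channel feature sets were chosen
over channel neighborhoods: with 11 widely spaced electrodes a neighborhood
would blur the map's spatial meaning. The cost is fixed at 1 per cell. For
group-level maps, `pool_subject_erps()` reduces each subject to at most five
averaged responses per class and pools them as observations, so the
searchlight can run across subjects on subject-level ERPs instead of single
trials.

## Inference: cluster-based permutation test

Single-subject significance uses label permutation with cluster correction:
the full decoding analysis is recomputed under `n_permutations` label
shuffles with the identical cross-validation schedule, so label exchange is
the only difference between observed and null runs. The point-wise
cluster-forming threshold is the 1 − α quantile of the permutation AUCs at
that time point, with the observed curve included in the threshold-forming
sample as the identity permutation — leaving it out makes the test
anti-conservative at small permutation counts, because each null curve is
then compared against a quantile it helped form while the observed curve is
not. Clusters are maximal contiguous supra-threshold runs scored by their
mass `sum(AUC - 0.5)` (cluster size is available via `cluster_stat`); the
null distribution is the per-permutation maximum cluster statistic; and each
observed cluster receives `p = (1 + #{null >= observed}) / (n_permutations
+ 1)`, so p is never zero and never below `1/(n_permutations + 1)`. The
family-wise error rate of this recipe is verified by simulation in the
acceptance suite (100 null sessions) at the binomial tolerance.

## The synthetic session generator

No public recordings accompany the method, so the package carries a
first-class generator whose defaults are the recording conditions the
pipeline targets:

* 512 Hz sampling, epochs spanning [−100, 600) ms (samples half-open on the
  right), 11-electrode 10/20 montage F3, Fz, F4, C3, Cz, C4, P3, Pz, P4,
  T7, T8, amplitudes in microvolts;
* two trial classes; deviant probability 0.15 with the oddball convention of
  no two consecutive deviants, implemented as a sequential draw that forces
  a standard after each deviant with per-draw probability p/(1 − p), which
  makes the long-run deviant rate exactly `p_deviant` (this caps
  `p_deviant` at 0.5; 0.5 yields strict alternation, used for balanced
  calibration fixtures);
* difference components as Gaussian bumps, parameterized by peak latency,
  FWHM and signed amplitude, truncated at ±3 sd and required to lie entirely
  post-stimulus: MMN at 190 ms, 80 ms FWHM, −3 µV; P3a at 300 ms, 100 ms
  FWHM, +4 µV; topography 1.0 at Fz/Cz, 0.7 at F3/F4/C3/C4, 0.4 at
  P3/Pz/P4, 0.2 at T7/T8;
* per-channel noise: white Gaussian (default sd 10 µV) plus 1/f "pink"
  background (default 5 µV), the latter via spectral shaping of white noise
  with an analytic variance normalization;
* multiplicative per-trial amplitude jitter `max(0, 1 + N(0, 0.1))` on top
  of a per-block gain profile, which is how waxing/waning sessions are
  constructed (e.g. gain `[0, 0, 0, 1, 0]` for a single responsive block).

The generator is deterministic: a config (including its seed) maps to a
byte-identical epoch set, and a session generated block-wise concatenates to
exactly the single-call result.

What it deliberately does **not** emulate: ocular or muscle artifacts,
cross-channel noise covariance (channels are independent), volume
conduction, stimulus-timing jitter, or drifting noise statistics within a
block. Tests passing on this generator therefore demonstrate the
correctness and calibration of the *method* under controlled conditions,
not robustness to every pathology of real bedside EEG.

## Preprocessing chain

The conditioning chain mirrors standard offline ERP practice: zero-phase
(forward–backward) Butterworth band-pass 0.1–30 Hz of order 4 — so an
effective 8th-order, 48 dB/oct zero-phase response — followed by a 2nd-order
band-stop of ±2 Hz around the 60 Hz line frequency; average-mastoid
re-referencing (mastoids dropped afterwards); baseline correction over
−100..0 ms; rejection of any trial exceeding ±75 µV on any channel;
superblock concatenation; undersampling. Filtering uses odd-symmetric
reflection padding against IIR edge transients and is best applied to
continuous data before epoching, since the 0.1 Hz high-pass settles over
seconds; per-epoch filtering is available but the padding can only mitigate,
not remove, edge effects on 700 ms segments. Rejection is evaluated after
filtering and baseline correction — thresholding drift-contaminated raw
epochs would reject on offsets the filter removes anyway; the chosen order
is recorded in the provenance log of every run.

## Numerical and design choices

* Sample standard deviation (n − 1) everywhere.
* Time axes are half-open `[start, end)` at exactly `1/sfreq` spacing.
* `time_decim` evaluates every d-th time point when full 512 Hz resolution
  is not needed (block tracking, permutation-heavy runs).
* Fold assignment, grouping and cost selection iterate over the classes in
  order of first trial occurrence, not factor-level order, so the random
  schedule is invariant under class renaming.
* Degenerate SVM fits (e.g. all-constant features in noiseless fixtures)
  fall back to zero scores, which the tie-aware AUC maps to 0.5.
* Amplitude extraction searches the MMN in 80–230 ms (most negative point)
  and the P3a in 250–350 ms (most positive), then averages the
  deviant-minus-standard difference wave over a peak-centered window (50 and
  100 ms respectively) clipped to the search window, over the Fz/Cz pair by
  default.
* Block-level "reliable" flags equal "at least one cluster with p ≤ α",
  exactly.

## Problem sizes in the shipped checks

The test and acceptance suites scale their simulations to desk-size runs:
chance-level calibration uses 400 balanced null trials with the full 5×10
cross-validation at 512 Hz resolution; the perfect-separation ceiling uses
200 noiseless trials; family-wise error is estimated over 100 null sessions
of 80 trials with 20 permutations each; latency recovery uses 20 sessions
of 500 trials; amplitude coupling uses 3 cohorts of 17 simulated subjects;
and wax/wane tracking uses 20 five-block sessions of 600 trials per block
with 39 permutations per block. These sizes are the package's choices for
routine verification; all of them enlarge cleanly through the same
configuration objects.

## Known limitations

* Single-channel searchlight cells inherit the coarseness of few held-out
  pseudo-trials; their per-cell AUCs are noisy and should be read as maps,
  not point estimates.
* The permutation test's minimum attainable p is `1/(n_permutations + 1)`;
  with 20 permutations a cluster is either "beats every null" or not.
* Undersampling discards standards once per dataset; a different draw can
  shift individual AUCs slightly (the repetitions average over folds and
  groups, not over the undersampling draw).
* The generator's independence across channels means spatial whitening or
  covariance-aware classifiers cannot be meaningfully evaluated against it.
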