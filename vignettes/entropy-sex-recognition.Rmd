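---
title: "Entropy features and a forest-to-logistic hybrid for EEG sex recognition"
author: "entrosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy features and a forest-to-logistic hybrid for EEG sex recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrosex)
```

## The problem and the model

Resting-state EEG carries individual traits, and one of them is sex:
across many scalp locations, female epochs tend to show *higher* signal
irregularity than male epochs when irregularity is quantified by
template-matching entropies. `entrosex` packages the full chain needed to
exploit this: preprocessing of multichannel recordings, per-epoch entropy
features, a hybrid tree-ensemble-to-linear classifier, and an evaluation
harness with robustness sweeps.

The classification unit is the **epoch**: a one-second window of a
multichannel recording. A cohort of 28 subjects (13 male, 15 female) with
five retained minutes at 1000 Hz yields 300 epochs per subject and 8400
epochs in total (4500 female, 3900 male), which is the dataset geometry the
synthetic generator reproduces by default.

### Entropy features

Four measures are computed per epoch and channel, all in nats:

* **Approximate entropy** (ApEn): $\Phi^m(r) - \Phi^{m+1}(r)$, where
  $\Phi^k(r)$ is the mean log fraction of length-$k$ templates within
  Chebyshev distance $r$ of each template, self-matches included. Always
  finite, but biased by the self-match.
* **Sample entropy** (SampEn): $-\ln(A/B)$ with $B$ the number of matched
  template pairs at length $m$ and $A$ at length $m+1$, self-matches
  excluded and both lengths counted over the same $N-m$ templates (this
  symmetric convention is what makes a constant series score exactly 0).
  With no matches the statistic is undefined; such cells are *flagged*, not
  imputed, and epochs carrying flags are dropped from model fitting with a
  logged count.
* **Fuzzy entropy** (FuzzyEn): the SampEn skeleton with each template
  centred on its own mean and the hard threshold replaced by the graded
  membership $e^{-(d/r)^n}$. The dimensionless $d/r$ argument is what
  makes the statistic exactly affine invariant when $r$ tracks the SD;
  smooth in $r$ and always finite for $r > 0$.
* **Permutation entropy** (PE): Shannon entropy of the ordinal-pattern
  census (order 4, delay 1 by default), ties ranked by order of appearance,
  normalized by $\ln(\text{order}!)$ into $[0, 1]$.

Parameters follow the standard choice for short physiological windows:
$m = 2$ and $r = 0.25 \cdot SD$, with the *population* SD computed per
epoch and channel, after filtering and before any normalization — each
one-second window is treated as its own approximately stationary segment.
Because $r$ tracks the SD and the distances are Chebyshev, ApEn, SampEn and
FuzzyEn are exactly invariant under affine transforms of the signal, and PE
is invariant under any strictly monotone transform; both invariances are
enforced by tests.

The estimators are implemented in C++ (exact $O(N^2)$ pair counting, no
approximations); the test suite pins them to naive double-loop R reference
implementations at $10^{-10}$.

### Preprocessing

The filter chain is the conventional EEG one: a 50 Hz mains notch
(second-order constrained biquad, quality factor 30 by default) followed by
a 0.15–45 Hz band-pass, both applied forward-backward so the phase is zero
and epoch boundaries stay aligned. The band-pass is realized as a cascade
of a 4th-order Butterworth high-pass (0.15 Hz) and a 4th-order low-pass
(45 Hz), each built from second-order sections: a direct
transfer-function band-pass at a normalized edge of $3\times10^{-4}$ is
numerically fragile (linearity degrades to about $10^{-5}$) and too
shallow (about 12 dB at 60 Hz), while the section cascade stays linear to
$10^{-12}$ and measures about 21 dB below the passband at 60 Hz with a DC
residual near 4%. The trailing five minutes of a recording are
retained (subjects need the first minutes to settle), and epochs that do
not fill a whole window are discarded, which is what makes the 300-epoch
count exact.

### Normalization and a leakage caveat

Features are min–max scaled into $[-1, 1]$. The protocol mode scales
**per subject** across the whole dataset before cross-validation; the
package reproduces it, but two caveats are documented deliberately:

1. Scaling before the CV split leaks test-fold statistics. A leakage-safe
   path is provided: fit the statistics on training data only
   (`minmaxNormalize(..., fitStats = )` reuses them, clipping test values
   into $[-1, 1]$).
2. Per-subject scaling erases between-subject *level* differences of every
   feature. On synthetic cohorts, where the sex effect lives exactly in
   that level, this removes most of the class signal (we measure holdout
   accuracy dropping from 1.00 to about 0.79). Recovery-oriented tests in
   this package therefore use **global** scaling, and the group-contrast
   check uses raw entropies; per-subject mode remains available as the
   protocol-replication setting.

### The hybrid classifier

A random forest (200 trees, depth cap 5, Gini splits, bootstrap resampling
with random feature subsetting) is fitted first. Each sample is then
re-represented by the **one-hot encoding of its leaves**: one column per
leaf of every tree, laid out tree-major with a stable depth-first (left
child first) leaf enumeration, so each row sums to exactly the number of
trees. A logistic regression with l1 penalty and inverse regularization
strength $C = 1$ is fitted on the concatenation
$[\text{leaf indicators} \mid \text{original features}]$. The forest thus
acts as a supervised, axis-aligned partitioner whose indicator basis lets
the linear model express piecewise-constant structure, while the untouched
original features preserve the smooth linear direction. Original features
arrive already in $[-1, 1]$ and leaf indicators are in $\{0, 1\}$, so no
further scaling is applied. Per-tree output weights are not modelled
separately: the logistic coefficients on each tree's leaf block subsume
them.

The solver is coordinate descent at the fixed penalty
$\lambda = 1/(nC)$ (the mapping between the C parameterization and the
per-observation-scaled penalty), warm-started along a short decreasing
path; it is deterministic, so end-to-end reproducibility is exact given
the forest seed.

## Evaluation harness

Generalization is estimated by a **nested** stratified 10-fold
cross-validation: the outer loop holds out one fold; inside each outer
training set an inner 10-fold grid search picks hyperparameters by mean
accuracy. The inner loop never touches outer-test samples, and the report
retains the index sets so tests can assert this. Grid tie-breaks are fully
specified (smaller tree count, then shallower depth, l2 before l1, then
larger $C$) because published protocols rarely state them. When no grid is
passed the defaults are used directly — the sweeps reuse defaults unless a
grid is supplied.

Fold assignment is at the epoch level by default, matching the protocol;
because every subject then appears on both sides of each split, a
**subject-grouped** mode is provided and used wherever the scientific
question is about unseen subjects. The no-signal null check is the clearest
case: subjects carry stable fingerprints (their oscillator frequency, their
regularity offset), so with epoch-level folds a classifier can re-identify
training subjects and score far above chance even when labels carry no
information. Under grouped folds, no signal provably means chance, which is
what that check asserts.

ROC curves sweep all distinct score thresholds with ties grouped; the AUC
is the trapezoidal area, identical to the normalized Mann–Whitney
statistic, and is pinned in tests both to a brute-force pair-counting
oracle and to an independent library implementation. Mean ROC curves
average vertically over a fixed 101-point false-positive-rate grid.

The per-feature group contrast uses **Welch's unpaired two-sample t test**.
(The groups — epochs of 13 male vs 15 female subjects — cannot be paired,
so a paired test is not applicable; note also that epoch-level tests treat
correlated epochs of one subject as independent, which overstates
significance. The exchangeability test of the generator therefore compares
per-subject means.)

Three robustness sweeps mirror the published protocol: electrode count
(random m-channel subsets, 10 draws per m), test fraction (stratified
holdout at each proportion), and sex ratio (the 27 subject-count cases
13:1 … 13:15 … 1:15). The evaluation inside a sweep is a repeated
stratified holdout at the default parameters; within the electrode sweep
the holdout split is held fixed per m so that the only repeat-level
randomness is the channel combination.

## The synthetic cohort

No recordings ship with the package; a generator stands in. Each channel
is a **regularity mixture**
$x(t) = \rho\,\mathrm{osc}(t) + (1-\rho)\,n(t)$: a unit-variance sinusoid
at a subject-specific alpha-band frequency (8–12 Hz, random phase per
channel) plus unit-variance pink noise (1/f spectral shaping of white
noise — deterministic given the seed, no filter warm-up). The regularity is
$\rho = \mathrm{clip}(\rho_{sex} + \text{subject effect} + \text{channel
jitter})$ with $\rho_{male} = \rho_0 + \delta$ and
$\rho_{female} = \rho_0 - \delta$; since template-matching entropies
decrease monotonically in $\rho$ (tested), a positive $\delta$ yields the
observed direction — female epochs more entropic than male. Defaults:
$\rho_0 = 0.5$, $\delta = 0.3$, subject SD 0.05, channel jitter 0.02.
$\delta$ is chosen once so the pipeline lands in the published performance
regime (near-ceiling accuracy); it was not fitted to any reported number.
Subject seeds are derived deterministically from the master seed, so
cohorts are bit-reproducible and subjects independent.

What the generator does *not* emulate: artifacts, volume conduction,
inter-channel covariance, task structure, or any physiological detail
beyond the entropy ordering. Passing tests on this cohort demonstrates
that the pipeline recovers a regularity-coded class difference end to end;
it says nothing about the effect size in real EEG.

## Numerical choices and degenerate inputs

* Natural logarithms everywhere; PE optionally normalized by
  $\ln(\text{order}!)$.
* A constant series has tolerance $r = 0$ (warned): ApEn and SampEn then
  score exactly 0; FuzzyEn requires $r > 0$, and the feature extractor maps
  that degenerate cell to 0.
* Ordinal ties rank by order of appearance (earlier index lower), making PE
  well defined on quantized signals.
* Constant features min–max-normalize to 0; test-time values outside the
  training range clip to the boundary.
* Decision threshold 0.5, boundary inclusive (a score exactly at the
  threshold is positive).
* Epoch windows are half-open sample intervals $[kN, (k+1)N)$, 0-based;
  trailing partial windows are dropped, never padded.
* EDF files are written/read with 16-bit sample quantization, so round
  trips are exact only to about range/$2^{16}$; the delimited format
  round-trips to $10^{-6}$ relative accuracy and is the fixture dialect.

## Problem sizes used by the shipped checks

The package's own verification runs at deliberately reduced scales, chosen
as the smallest sizes at which every qualitative claim is stable: the
dataset-geometry check simulates the full 28-subject, 30-channel, 300 s,
1000 Hz cohort (streamed subject by subject); the recovery and ordering
checks use 28 subjects, 6 channels, 60 s at 200 Hz (1680 epochs, 24
features); oracle suites use 50 random series of lengths 50–300. All
seeds are fixed.

## Worked example

```{r example, eval = FALSE}
cfg <- cohortConfig(nChannels = 6, fs = 200, durationS = 60, seed = 101)
coh <- generateCohort(cfg)
ep  <- do.call(bindEpochSets, lapply(coh$recordings, segmentEpochs))
fm  <- extractFeatures(ep)                      # 1680 epochs x 24 features
cmp <- compareGroups(fm)                        # female vs male, per feature
fmN <- minmaxNormalize(fm, "global")
X   <- featureValues(fmN); y <- epochLabels(fmN)
rep <- nestedCV(X, y, classifier = "hybrid", seed = 101)
rep
```

## Known limitations

* The generator's sex effect is a single global regularity shift; real
  effects are regional and far smaller.
* Epoch-level cross-validation measures within-cohort discrimination, not
  generalization to new subjects; use `groups =` for the latter.
* Per-subject min–max scaling and epoch-level folds together let subject
  identity do classification work; both caveats are inherent to the
  replicated protocol and are documented rather than silently fixed.
* The EDF writer covers the continuous 16-bit subset of the format only.
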