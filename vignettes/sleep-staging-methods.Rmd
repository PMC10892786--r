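---
title: "Methods: single-channel EEG sleep staging with swarm-tuned boosting"
author: "somnoboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel EEG sleep staging with swarm-tuned boosting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoboost)
```

## The problem

Polysomnography scores sleep in 30-second epochs, each labelled with one of
five stages: wake (W), light NREM sleep (N1, N2), slow-wave sleep (SWS,
merging the older R&K stages N3 and N4) and REM. somnoboost classifies these
epochs automatically from a *single* EEG channel sampled at 100 Hz — the
setting of wearable and home sleep monitors, where a full montage is not
available. The classifier is a gradient-boosted tree ensemble whose
hyperparameters are tuned by particle swarm optimisation (PSO), trained on
hand-crafted features of each epoch and of its immediate temporal
neighbourhood.

## Pipeline and stage conventions

1. **Input.** An EDF signal file and a hypnogram (EDF+ annotations or a
   plain `epoch<TAB>stage` TSV). Raw stages N3 and N4 are merged into SWS;
   epochs scored `?` (ungraded) or `MOVEMENT` are dropped together with
   their 30 s of signal; leading and trailing wake runs are truncated to at
   most `wakeBuffer` minutes (default 30) around the first and last non-wake
   epoch. The 30-minute default is a deliberate design choice: the
   convention in the field is to keep *some* peri-sleep wake so the W class
   is represented, but not hours of lights-on recording; the buffer is
   symmetric and configurable because no single value is canonical.
   Internally stages are coded W=0, N1=1, N2=2, SWS=3, REM=4.
2. **Preprocessing.** A 0.5–49.5 Hz linear-phase FIR band-pass
   (hamming-window design) removes drift and mains/high-frequency content;
   the signal is cut into non-overlapping 30-s epochs (3000 samples at
   100 Hz; a trailing remainder is dropped) and z-scored *per recording*
   (pooled mean/SD), because the purpose of normalisation is to equalise
   amplitude across subjects, not to flatten within-night dynamics.
   Filtering precedes epoching so that epoch boundaries do not introduce
   transients.
3. **Sub-bands.** Each epoch is decomposed by nine zero-phase FIR
   band-passes: δ 0.5–4, θ 4–8, α 9–11 (the adult posterior rhythm), σ
   12–15 (spindles), β1 14–20, β2 20–30, γ1 30–40, γ2 40–49.5, and a
   K-complex band 0.5–1 Hz that deliberately overlaps δ. A 13–20 Hz
   variant of β1 circulates as well; this package fixes 14–20 Hz as the
   canonical machine-readable value and leaves the table configurable
   (`defaultBands()`, `readBandTable()`).
4. **Features.** 52 per epoch (`sleepFeatureNames()`): subject age; 24
   whole-epoch statistics (population moments, median, absolute maximum,
   RMS, peak-to-peak amplitude, zero-crossing rate, Hjorth mobility and
   complexity, five entropies, Lempel–Ziv complexity, maximum–minimum
   distance, three fractal dimensions, DFA and Hurst exponents, total PSD);
   and per-sub-band energy, Welch band power and peak-to-peak amplitude
   (9 × 3). Age is included because spectral composition drifts with age
   and helps separate subjects' baselines.
5. **Feature shifting.** Every non-age column is duplicated with a one-epoch
   lag and lead (`.lag1`, `.lead1`), giving 3 × 51 + 1 = 154 columns. Sleep
   stages persist across epochs, so the neighbours' features carry real
   information. Shifting never crosses recording boundaries; at a
   recording's ends the missing context is filled by replicating the
   terminal row — replication avoids artificial discontinuities that
   zero-filling would create, and refusing to borrow across recordings
   prevents cross-subject leakage.
6. **Evaluation.** Stratified 10-fold cross-validation over pooled epochs;
   per fold the *training* rows only are oversampled to class balance
   (random duplication with replacement — synthetic interpolation is
   deliberately avoided as it would fabricate epochs), a 5-class softmax
   boosted ensemble is trained, and accuracy, support-weighted
   F1/precision/recall, Cohen's κ, the 5×5 confusion matrix, one-vs-rest
   AUC and multiclass logloss are recorded. Weighted (by class support)
   averaging is used for F1/precision/recall; on imbalanced data this is
   the averaging mode under which the four headline metrics track each
   other closely.

## Feature definitions: conventions that matter

* **Population moments.** Variance, skewness and kurtosis all use the 1/M
  normalisation; kurtosis is non-excess (a Gaussian scores ≈ 3).
* **Zero-crossing rate** counts strict sign changes
  (`x[i] * x[i-1] < 0`) divided by M−1; exact zeros do not count.
* **Hjorth parameters** use the first difference as the derivative, so
  mobility is in radians-per-sample terms: `sqrt(var(Δx)/var(x))`;
  complexity is the mobility of the difference over the mobility of the
  signal.
* **Histogram entropy** needs a discretisation: an equal-width 10-bin
  histogram over the observed range (configurable). Since the bin grid
  follows the observed range, the value is invariant under affine
  amplitude rescaling and responds to distribution shape only — a property
  the tests pin down.
* **Permutation entropy**: order 3, delay 1; ties broken by temporal order.
  **Sample entropy**: m = 2, tolerance 0.2 × SD, self-matches excluded;
  when no template pairs match, the value is capped at the most
  informative resolvable level, `log(choose(n-m, 2))`, and flagged.
  **SVD entropy**: 10 × 1 delay embedding. **MMD**: 1-s (100-sample)
  windows, summed. **Higuchi**: kMax = 10. None of these knobs has a
  single canonical value in the literature; the defaults above are the
  common ones and all are recorded in `featureParams()`.
* **Petrosian fractal dimension** uses the standard ratio form
  `log M / (log M + log(M / (M + 0.4K)))` (K = sign changes of the first
  difference). A circulating variant omits the ratio inside the second
  logarithm; that form is degenerate (it cannot equal 1 for monotone
  signals), so the standard form is implemented.
* **Welch PSD**: 4-s hamming segments, 50% overlap, mean-detrended,
  one-sided density scaled so its integral reproduces the signal variance.
  Band powers are trapezoidal integrals of this density (with edge
  interpolation so adjacent bands tile additively); the scalar "PSD"
  feature is the total 0.5–49.5 Hz power. Computing band powers from the
  PSD rather than from filtered-signal variance is cheaper and
  deterministic; the two agree within filter leakage.
* **Natural logarithms** everywhere; entropies are in nats.

## Numerical choices

* **FIR design.** Hamming-window design with the order set by the 3.3/N
  transition-width rule. The transition bandwidth is
  `min(max(0.5, low/2), (high − low)/2, 3)` Hz — never wider than half the
  band (so narrow bands like α 9–11 keep a flat passband) and never wider
  than 3 Hz. Filters are applied by FFT convolution with exact group-delay
  compensation (linear phase ⇒ integer delay), so filtering is zero-phase
  and epoch alignment is preserved; signals are edge-padded by sample
  replication to suppress boundary transients. Designed filters and their
  spectra are cached across epochs.
* **Degenerate inputs.** Zero-variance epochs are an error during assembly
  (named with feature and epoch); zero-variance signals inside individual
  features are either defined (histogram entropy 0, KFD 1) or flagged
  degenerate (Hjorth ramp case, sample-entropy cap).
* **Probability clipping.** Multiclass logloss clips probabilities to
  `[1e-15, 1 − 1e-15]`.
* **Tie-breaks.** Argmax class prediction uses first-index tie-breaking so
  runs are bit-reproducible; ordinal patterns break ties by temporal order;
  window extrema use the first occurrence.
* **Seeding.** One master seed fans out to named child streams (folds,
  balancing per fold, training per fold, swarm init, swarm motion) via a
  fixed integer hash, all kept below 2^31; identical seeds reproduce
  experiments exactly, including JSON reports.

## The PSO tuner

Hyperparameters of the boosted ensemble (booster type, learning rate, tree
depth and count, child weight, split loss γ, subsampling, column sampling,
L1/L2 penalties, and the dart dropout extras) span a mixed
continuous/integer/categorical space. Particles live in a continuous
internal representation: integer axes are rounded at evaluation time and
categorical axes occupy unit cells `[i, i+1)` decoded by flooring. The
swarm starts uniformly within bounds with zero velocities; each iteration
updates velocity per dimension with inertia ω, cognitive c1·r1 attraction
to the personal best and social c2·r2 attraction to the global best (fresh
`r1, r2 ~ U(0,1)` per particle per dimension), then moves the particle,
clamping velocity to half the axis range and position to the bounds. The
stopping criterion is the iteration budget; the global best is monotone by
construction. Defaults are the constriction-equivalent ω = 0.7298,
c1 = c2 = 1.49618, swarm 20, 30 iterations.

The fitness of an assignment is mean *training-data* accuracy under an
inner stratified 3-fold CV (balanced training folds), so the tuner never
sees outer test folds' role. The tuner runs once before the outer loop —
tuning is a one-time process in this design — which means the tuned
configuration has seen the pooled data through the inner CV; a fully
nested protocol (re-tuning per outer fold) would multiply cost by k and is
not what this method prescribes. A failed evaluation scores −∞ and the
search continues.

The boosted-tree machinery itself (softmax objective, regularised leaf
scores, additive fitting) is delegated to the xgboost engine with an exact
parameter mapping; the package reimplements only the reported quantities
(multiclass logloss, κ, CV means) for evaluation.

## The synthetic generator

`synthSleepDataset()` emulates the features of overnight EEG this pipeline
relies on, with every default chosen once as a plausible desk-scale
stand-in:

* **Markov stage dynamics** with a persistence-heavy transition matrix
  (diagonal 0.62–0.85; N1 as a transient gateway, N2 the hub) so temporal
  context genuinely helps — this is what makes the feature-shifting
  comparison meaningful.
* **Stage-conditional spectra**: W = α (20 µV) + β1 (10 µV); N1 = θ
  (15 µV); N2 = θ (8 µV) + two 1-s σ-spindle bursts at 13.5 Hz + one
  biphasic 0.7 Hz K-complex pulse per epoch; SWS = δ (40 µV); REM = θ
  (10 µV) + β2 (8 µV). Band sinusoids get ±20% frequency and amplitude
  jitter and random phase per epoch.
* **1/f background noise** (exponent 1, 15 µV RMS in the "easy" preset)
  and a per-subject amplitude factor (log-uniform 0.8–1.25) that the
  per-recording normalisation must undo; ages drawn uniformly from 20–60
  years. The "hard" preset halves the spectral contrasts and doubles the
  noise.

What passing tests on this generator show: the pipeline extracts the
spectral and temporal structure it was designed to extract, end to end,
and the tuner and evaluation protocol behave correctly. On the easy
preset the spectral features alone are close to sufficient, so the
measured contribution of feature shifting there sits near the ceiling; to
pin down the shifting *mechanism*, a dedicated check gives N1 the exact
spectral profile of REM — instantaneous features then cannot separate the
two, and only the lag/lead context (REM persists, N1 is transient) can,
which it demonstrably does. What the tests do not show: performance on
real EEG, whose stage boundaries are fuzzy, artefact-laden and
scorer-dependent; real N1 in particular is far harder than any sinusoid
mixture. Desk-scale synthetic accuracy is therefore a pipeline check, not
a clinical claim.

## Problem sizes used in checks

The bundled end-to-end checks use 5 subjects × 400 epochs (2000 epochs) of
the easy preset, stratified 10-fold evaluation, and a reduced tuning budget
(compact search space, swarm 6 × 5 iterations over an inner 3-fold CV) —
sizes chosen so the whole suite runs comfortably on a single CPU while
still exercising every stage of the method at realistic dimensionality.
Unit checks verify every feature against independent brute-force oracles
on dozens of random short signals.

## Known limitations

* The EDF layer targets 16-bit EDF/EDF+ as produced by common PSG
  archives and by its own writer; exotic variants (discontinuous EDF+D,
  multi-annotation channels) are out of scope.
* No artefact rejection (eye movement, muscle) is performed beyond the
  band-pass; inputs are assumed reasonably clean or pre-cleaned.
* Recordings are expected at 100 Hz; other rates are accepted by the
  feature layer but the MMD/Welch defaults are expressed in seconds and
  scale accordingly — resampling is not provided.
* Pooled-epoch cross-validation estimates within-cohort generalisation;
  a per-subject split (leave-subjects-out) is stricter and available by
  constructing folds from `recording_id`, but it is not the protocol this
  method reports.
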