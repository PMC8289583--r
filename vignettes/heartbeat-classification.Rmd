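---
title: "Heartbeat classification with attributable features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat classification with attributable features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adabeat)
```

# The method

`adabeat` classifies single heartbeats from two-lead ECG into the five
ANSI/AAMI EC57 classes — N (non-ectopic), S (supraventricular ectopic),
V (ventricular ectopic), F (fusion), Q (unknown/paced) — using features a
cardiologist can read off a strip chart ("attributable" features), combined
by an AdaBoost ensemble of random forests. This vignette explains the model,
the tunable parameters, the numerical choices, and what the synthetic
validation does and does not establish.

## Preprocessing

**Denoising.** Baseline wander (electrode drift, respiration; sub-Hz) is
estimated by a two-stage running median — 200 ms, which is flat across P
waves and QRS complexes, then 600 ms, which is flat across T waves — and
subtracted when material (RMS above 5% of signal RMS; the gate keeps the
operation idempotent on already-clean signals). High-frequency noise (white
noise, 50/60 Hz powerline) is removed by soft-thresholding the two finest
detail bands of a periodized db6 wavelet decomposition — everything above
roughly 45 Hz at 360 Hz sampling — at the universal threshold
`sigma * sqrt(2 log n)` with `sigma = MAD(d1)/0.6745`. The band carrying the
P-QRS-T morphology (about 0.7–45 Hz) is untouched. db6 is chosen for its
regularity and QRS-like shape; the decomposition is implemented with
circular convolution so it is exactly orthogonal (Parseval holds to machine
precision) and inversion is exact.

**R-peak detection.** The detection function is the maximum absolute
Mexican-hat CWT coefficient across four scales spanning 12–30 Hz — the band
where QRS energy dominates both the slower P/T waves and high-frequency
noise. Local maxima above `k = 4` times the median absolute detection value
are candidates; candidates closer than the 200 ms refractory period are
resolved toward the stronger one (then the earlier on ties); a candidate
within 360 ms of a preceding candidate with less than half its detection
amplitude is discarded as a T wave (the classic Pan–Tompkins rejection
rule); survivors are refined to the signal extremum within ±50 ms. All of
scale band, `k`, and the refractory period are arguments of
`detect_r_peaks()`.

**Delineation.** QRS onset/offset are found by walking outward from the R
peak until the excursion from the isoelectric level (zero, after baseline
removal) decays below 1.5% of the R amplitude — for a Gaussian-like wave
this lands within 0.1 standard deviations of the 3-sigma boundary, i.e.
within a few milliseconds. P waves are searched 200→40 ms before QRS onset
(never earlier than the previous beat's T offset, so short coupling
intervals do not turn the previous T wave into a fake P), T waves 80→400 ms
after QRS offset (never beyond 80 ms before the next R). A wave whose peak
excursion is under `min_wave_amp = 0.04` mV is flagged undetected rather
than fabricated — deliberately, because an absent P wave is itself a
discriminative signal for S/V/Q beats.

## Features

| Set | Content | Length | Units |
|-----|---------|--------|-------|
| A | lead-A window, 90 samples before R to 144 after | 235 | mV |
| B | lead-A window ++ lead-B window | 470 | mV |
| C | P/QRS/T wave intervals, PR segment, ST-T, QT, RR | 7 | s |
| D | QRS area over `[qrs_on, qrs_off]`, baseline-corrected | 1 | mV·s |
| E | db6 wavelet coefficients of the lead-A window | 240 | mV |

Each interval is a fiducial-index difference divided by the sampling rate.
The QRS-area baseline is the PR-segment mean (the 20 samples before QRS
onset when no P wave exists), which makes the area invariant to constant
offsets. Set E uses a level-4 decomposition: a 235-sample window supports at
most a handful of dyadic levels, and at level 4 the coefficient blocks span
roughly 11–180 Hz plus an approximation below 11 Hz, which covers the QRS
band; the window is zero-padded to 240 samples (the next multiple of 2^4),
and the level is configurable. Whether interval/area/wavelet features should
use one or both leads is genuinely open; they are computed on lead A (the
lead conventionally used for beat detection), and the morphology sets carry
the lead-B information.

Intervals involving an undetected wave are imputed with the per-record
median of that interval — this keeps the feature matrix rectangular without
dropping beats, and the imputed cells are recorded in the `imputed`
attribute. The RR interval of a record's final beat repeats the previous RR.

## The ensemble

Boosting follows the classical recursion: weighted error
`e_m = Σ w_j I(G_m(x_j) ≠ y_j)`, round vote `α_m = ½ ln((1−e_m)/e_m)`,
multiplicative reweighting `exp(±α_m)` normalized by `z_m`. Three choices
deserve comment:

* **Multiclass extension.** The ±1 formulation generalizes here as a
  SAMME-style weighted vote with the binary α kept as written. With
  random-forest base learners `e_m` stays far below the multiclass no-harm
  bound, so the missing `log(K−1)` term of full SAMME never matters in
  practice; the plain form is used because it matches the printed recursion.
  Ties in the final vote break in the fixed class order N, S, V, F, Q.
* **Imbalance handling.** Each round's bootstrap keeps every sample of
  classes below the uniform share (count < N/5) and fills the remainder by
  weight-proportional draws from the larger classes. Minority beats are
  therefore in every base learner's training set, while boosting reweights
  toward whatever the previous round got wrong.
* **Degenerate rounds.** `e_m` is clamped to `[1e-10, 1−1e-10]` so a perfect
  base learner gets a large finite vote instead of an infinite one. A round
  with `e_m > 0.5` resets the weights to uniform and redraws its bootstrap
  without advancing the round counter, up to 5 retries, after which training
  aborts with an error naming the round.

Defaults: 10 rounds, 70 trees per forest (the optimum of the published
tree-count sweep over 20–90), `mtry` left to ranger's `sqrt(p)`. A single
seed drives label sampling, bootstraps, forests (including prediction
tie-breaking, which ranger otherwise randomizes) and the train/test split,
so a run is reproducible from its manifest.

## Evaluation

One-vs-rest counts from the 5×5 confusion matrix use the standard
orientation — FN is the row off-diagonal (true class predicted elsewhere),
FP the column off-diagonal — which is the orientation that reproduces the
published per-class sensitivities and positive predictivities of this
method's benchmark results. Percentages are rounded half-up to two decimals;
a zero-denominator metric is reported as `NA`, never as 0. The 90/10 split
is stratified per class (the benchmark description says only "random");
stratification guarantees all five classes appear in the test set, matching
the published per-class test counts in spirit, and can be disabled with
`stratify = FALSE`.

## The synthetic generator

`synth_ecg()` emulates the properties of the MIT-BIH arrhythmia material
that the pipeline depends on: 360 Hz sampling; two leads with different
per-wave gains and QRS polarity (lead B defaults to
`p = 0.5, qrs = −0.4, t = 0.6`, emulating the II-vs-V1 contrast); beats as
sums of three Gaussian bumps whose amplitude/width/offset differ by class
(S: premature with absent P; V: wide, tall, P-less with discordant T;
F: intermediate fusion morphology; Q: wide low-slew paced-like complexes);
5% amplitude and 3% width jitter per wave; RR intervals from per-class
truncated normals (floor 0.3 s, so beats never overlap); class proportions
defaulting to the benchmark's own imbalance (82.8 / 2.5 / 6.6 / 0.7 / 7.3%);
and additive baseline wander (0.1 mV at 0.25 Hz), powerline interference
(0.02 mV at 50 Hz) and white noise (0.02 mV SD). Gaussian bumps were chosen
over a dynamical ECG model because their fiducials are known analytically
(the 3-sigma points), which turns the generator into an exact oracle for
detection and delineation.

What passing the synthetic suite shows: the equations and algorithms are
implemented correctly — boundaries land where they analytically must,
detection attains its specified operating point, features equal their
closed forms, the ensemble follows the printed recursion. What it does not
show: clinical performance. Real beats have non-Gaussian waves (notched QRS,
biphasic T), rhythm context (bigeminy, runs), electrode artifacts and
inter-patient variability the generator deliberately omits, and the
near-perfect synthetic accuracies should be read as "the classes are
separable as constructed", not as a clinical claim. The published benchmark
figure (99.11% overall on MIT-BIH with sets B+C+D+E) is represented in the
package by its confusion matrix (`mitbih_reference_confusion()`), from which
all published per-class metrics are recomputed exactly; re-running the full
benchmark requires the PhysioNet download.

## Problem sizes and numerics

The test suite and acceptance script run at desk scale, chosen to exercise
every code path with comfortable statistical margins: 500-beat records for
detection (F1 ≥ 0.99 at ±5-sample tolerance), 10,000 labels for
class-frequency convergence (±1.5% absolute), 3,000 beats / 10 rounds /
70 trees for the end-to-end benchmark (held-out accuracy ≥ 95% and strictly
above the QRS-area-only configuration). Numerical tie-breaks are all fixed
and documented: candidate R peaks by amplitude then index; stump splits by
feature order, then threshold, then class order; ensemble votes by class
order. The WFDB writer quantizes at gain 200 adu/mV into 12-bit format 212,
so round-trips are exact to 2.5 µV.

## Known limitations

* Delineation assumes a single dominant excursion per wave; heavily notched
  or biphasic waves will delineate at the dominant lobe.
* Interval imputation by the record median blurs class contrasts when a
  class systematically lacks a wave — intentional (the P-absence flag keeps
  the information), but a different sentinel can be injected upstream.
* The WFDB codec covers the subset used here: format 212, one or two
  signals, beat annotations with SKIP extensions; it is not a general WFDB
  implementation.
* Detection parameters are tuned for adult beat morphology at 360 Hz;
  other sampling rates rescale automatically, but unusual morphologies may
  need the `freq_range`/`k` arguments.
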