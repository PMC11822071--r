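---
title: "Discriminating cognitive load from multimodal physiology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating cognitive load from multimodal physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

Cognitive-load theory distinguishes *intrinsic* load (ICL), driven by the
inherent complexity of the material, from *extraneous* load (ECL), driven by
distracting presentation elements. `cogload` implements a complete pipeline
for asking whether cheap, continuous physiological channels -- gaze
position, pupil diameter, a finger-sensor heart-rate pulse and galvanic skin
resistance, all sampled at 150 Hz -- can discriminate the two load types and
their levels on single trials. The study design it targets crosses two
tasks with two difficulty levels: mental calculation (ICL; short vs. long
operands define low vs. high load, 24 trials per participant) and visual
search among Gabor patches (ECL; parallel vs. serial search define low vs.
high load, 20 trials per participant), with 33 participants and a backward
digit-span score as a working-memory covariate.

Because the original recordings are an external deposit, the package ships
a first-class synthetic generator that emulates the study design, so every
stage -- event detection, feature extraction, reliability, modelling,
evaluation -- is exercised end to end by code alone.

## From raw streams to predictors

**Fixations and saccades.** Gaze is segmented with the classic
dispersion-threshold algorithm (I-DT): a sample window grows while
`(max x - min x) + (max y - min y)` stays at or below the threshold, and is
emitted as a fixation once it covers the minimum duration. Defaults are
1.0 degree of visual angle (about 40 px at the default geometry: 21.5-inch
1920x1080 monitor viewed from 570 mm) and 100 ms -- conventional I-DT
settings. Durations are frame-inclusive (offset = last sample + one
sampling interval), so a k-sample fixation lasts k/150 s. Runs of up to 3
invalid samples are bridged by linear interpolation; longer gaps terminate
the window. Saccade amplitudes are Euclidean distances between consecutive
fixation centroids.

**Outlier reduction.** Within each participant-by-task scope, fixation
durations and (separately) saccade amplitudes above `mean + 1 IQR` are
reduced to the largest non-outlying value (upper tail only, single pass,
type-7 quantiles). The grouping scope is a package choice: per participant
and task, before any aggregation, so that one participant's heavy tail
cannot leak into another's trial means.

**The K coefficient.** For fixation `i` with duration `d_i` and following
saccade amplitude `a_{i+1}`,
`K_i = (d_i - mu_d)/sd_d - (a_{i+1} - mu_a)/sd_a`, and a trial's K is the
mean of its `K_i`. Positive values indicate focal, negative ambient
attention. The moments are taken per participant within task, over paired
events only; this makes the scope-wide mean of `K_i` exactly zero, while
trial-level values remain informative for the trial-level classifier.

**LHIPA.** The Low-High Index of Pupillary Activity summarises the balance
of low- against high-frequency pupil oscillations. The pupil series is
decomposed with a periodized DWT (symlet-16 by default; no R wavelet
package is available, so the transform is implemented here and verified
against a brute-force oracle). The high-frequency band is the level-1
detail, the low-frequency band the level `floor(log2(n)/2)` detail; the LF
coefficients are divided by time-aligned HF coefficients, modulus maxima of
the ratio are thresholded by `lambda = sigma * sqrt(2 ln m)`, and the index
is the surviving-maxima count per second.

Two numerical consequences of the 150 Hz rate deserve emphasis. First, for
a 3-s trial the prescribed levels put the "high" band at 37.5-75 Hz and the
"low" band at 4.7-9.4 Hz, so effortful pupillary activity in the
conventional 1-4 Hz range loads the *numerator*: the trial-level index
rises with that activity, which is also the direction the study data show.
Second, the noise scale `sigma`: any estimate proportional to the ratio
itself (SD of the maxima, MAD of the ratio) makes the count scale-invariant
and therefore insensitive to the very band balance the index is meant to
measure. The default is therefore `sigma = 1` -- the ratio of two
same-scale coefficient bands is dimensionless, and the fixed threshold
`sqrt(2 ln m)` counts epochs in which LF coefficients dominate HF
coefficients by a fixed factor. This choice keeps the index strictly
monotone in added high-band power (verified over 100 seeded runs); the
data-driven estimators remain available via `lhipa(..., sigma = )`.

**Pupil dilation.** Percent change of the mean trial pupil diameter
against the participant's pre-task baseline screen. Percent (rather than
raw millimetre difference) matches the magnitude of the published
condition means (about +/-5 with SDs near 10).

**Heart-rate variability.** Pulse peaks are local maxima with prominence
at least 0.25 x (95th - 5th percentile of the trial's signal) and at least
0.33 s apart (the physiological refractory floor). Successive peak-time
differences give inter-beat intervals; a centred 3-beat moving average
(shrinking to 2 beats at the edges) suppresses finger-movement noise; HRV
is the sample SD of the smoothed series. No installed R package provides
prominence-based peak picking, so the detector is implemented here.

**GSR.** Mean skin resistance (Ohms) over the trial; means outside the
plausible 10 kOhm - 2 MOhm range are retained but flagged.

## Reliability, model and evaluation

**Split-half reliability.** Per feature and group, each participant's
trials are randomly split into halves (an odd trial joins a random half),
per-participant half-means are correlated across participants, and the
Spearman-Brown correction `2r/(1+r)` is applied; 5000 random splits by
default. Negative correlations are corrected as-is; only pathological
`r < -0.5` is clamped into [-1, 1] and counted.

**The discriminant model.** Eight predictors in fixed order (fixation
duration, saccade amplitude, K, HRV, GSR, LHIPA, pupil dilation, digit
span) are standardized with training moments after an unstratified 80/20
trial-level split (matching the published trial-level priors; rows with
any missing predictor are dropped with a logged count). The four-group
linear discriminant solves `B a = lambda W a` through the Cholesky-whitened
symmetric form; axes are scaled to unit pooled within-class variance and
signed so each axis's dominant coefficient is positive; eigenvalues give
the proportions of trace. Near-singular pooled covariance receives a ridge
of `1e-8 tr(W)/p`. Posteriors are shared-covariance Gaussian posteriors;
two preliminary two-group models (load type; load level) reuse the same
machinery. The implementation is cross-checked against an independent
reference implementation in the test suite.

**Evaluation.** Confusion matrix; one-vs-rest sensitivity, specificity,
balanced accuracy, precision, recall, F1 (zero denominators are reported
missing, never zero); overall accuracy with the exact Clopper-Pearson
interval and a one-sided exact binomial test against the no-information
rate; Cohen's kappa; and ROC/AUC for low-vs-high within each task, scored
by the posterior probability of that task's high-load class (posteriors,
not raw discriminant scores, are the default). Reports round to 3 decimals;
internal values keep full precision.

## What the generator emulates -- and what it does not

Each trial is a scanpath of complete fixations (lognormal durations)
separated by ballistic saccades (lognormal amplitudes, main-sequence
durations of about 21 ms + 2.2 ms/deg), with Gaussian within-fixation
scatter; a pupil channel (baseline + condition offset + slow sinusoid +
band-limited 1.2-4 Hz component + white noise); a raised-cosine pulse train
whose inter-beat intervals carry a slow sinusoidal modulation (respiratory
sinus arrhythmia) plus jitter; and a tonic skin-resistance level with slow
drift. Trials end at a fixation boundary (responses terminate a trial at
the end of a fixation), so detected event distributions recover the
configured ones. Participants carry stable traits -- pupil baseline,
multiplicative offsets on oculometric and biometric levels, a digit-span
score drawn Normal(7.24, 1.02) and rounded -- which create the
between-participant variance that split-half reliability measures.

Condition defaults are calibrated to the published per-condition feature
means (fixation duration, saccade amplitude, pupil dilation, HRV, GSR
levels); this calibration is necessarily approximate, since the published
table reports feature-level statistics after detection and winsorization,
not generative parameters. An `effect_size` multiplier interpolates every
condition parameter toward the across-cell mean: `effect_size = 0` yields
a null dataset on which the classifier must not beat the largest prior.

Three stated simplifications:

* **Gaze noise.** The tracker's precision is not reported for this setup;
  the default scatter SD is 0.08 degrees. Substantially noisier scatter
  (e.g. 0.25 degrees) is incompatible with the 1.0-degree I-DT sum-of-ranges
  threshold -- expected window dispersion alone would exceed it and no
  fixation would survive -- so the default keeps generator and detector
  mutually consistent.
* **Saccade kinematics.** Flight samples are placed in the interior of the
  saccade path, at least about 1.1 degrees from both endpoints (sub-2.2-degree
  saccades complete between samples). Real velocity profiles place samples
  near endpoints, where they pollute dispersion windows and split a few
  percent of fixations; the simplification makes the synthetic scanpath
  unambiguous for dispersion-based parsing. Passing recovery tests
  therefore certify the detector on clean scanpaths, not its behaviour on
  real saccade tails.
* **No stimulus rendering or response correctness.** Only physiological
  streams and labels are simulated; VST durations are response-terminated
  and drawn lognormal with serial search longer than parallel (about 4.5 s
  vs. 2.6 s), values the design implies but does not state.

Consequently, green tests demonstrate that the pipeline recovers known
structure from signals with the assumed statistical shape; they cannot
certify behaviour on vendor-specific artefacts (blinks, tracking loss
bursts, motion artefacts in the pulse channel) beyond the invalid-sample
bridging exercised in tests.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) everywhere.
* Fixation durations: frame-inclusive; ties in the I-DT prefix are
  resolved by the monotonicity of window dispersion.
* LHIPA: internal NA runs interpolated; constant series return 0 with a
  warning; series under 16 usable samples return NA; zero HF coefficients
  are floored at a relative epsilon before division.
* Peak thinning: candidates are kept highest-first under the minimum
  distance, a deterministic rule.
* Missing features are NA plus a `*_missing` flag; they exclude a trial
  from the predictor matrix (logged), never silently zeroed.
* Eigen-solution on the symmetrized whitened problem; equal eigenvalues
  are ordered deterministically by the underlying LAPACK ordering; axis
  signs fixed by the dominant-coefficient convention.
* All stage seeds derive from one pipeline seed (dataset, reliability
  schedule, train/test split), making reports byte-reproducible.

## Problem sizes used by the test suite

Unit tests run on reduced designs (2-8 participants); the distribution
recovery checks use 200 trials per condition; the LHIPA monotonicity and
I-DT oracle checks use 100 seeded instances each; the reliability null and
analytic checks use 33 and 120 simulated participants; the end-to-end
acceptance check runs the full 33-participant design twice (reproducibility
and timing) plus four reduced 12-participant seeds for the
direction-of-effect margin. These sizes are the package's chosen balance
between statistical resolution and a test suite that stays pleasant to run.

## Known limitations

* The synthetic calibration targets first moments per condition; joint
  feature dependencies within trials (e.g. pupil-HRV coupling) are not
  modelled.
* Reported reliability ranges from the study depend on its human data and
  are not reproduction targets; the package verifies the estimator's
  contracts instead.
* The LHIPA normalisation in the literature is not fully specified; the
  package's unit-scale threshold is a documented, config-exposed choice,
  and absolute index magnitudes should not be compared across
  implementations.
* GSR enters as resistance (Ohms), matching the published units; a
  conductance option is out of scope.
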