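---
title: "Estimating longitudinal motor-skill change from resting-state EEG connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating longitudinal motor-skill change from resting-state EEG connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracefc)
```

## The problem

A person practicing a fine motor task — here, tracing a curved pattern on a
screen with a computer mouse — improves gradually over days. `tracefc`
implements an *individualized* procedure for estimating that longitudinal
change from resting-state EEG functional connectivity (rsFC): for a single
participant with six to eight training sessions, it learns which electrode
pairs and synchronization frequencies co-vary with that participant's tracing
error and builds a small regression model that predicts the error of a
held-out session from a five-minute resting recording alone.

The pipeline has three stages, mirrored by the package's modules:

1. **Tracing performance** — an eight-section quarter-ellipse track is scored
   against the recorded pointer trajectory; sessions are summarized by error
   medians.
2. **Connectivity** — a Morlet filter bank turns 32-channel EEG into
   peak-detected synchronization indices for all 496 electrode pairs at 15
   center frequencies, with five estimators (phase clustering/PLV, spectral
   coherence, imaginary coherence, PLI, weighted PLI).
3. **PLS brain–behavior modeling** — partial-least-squares correlation with
   permutation screening and bootstrap-consensus channel selection, followed
   by PLS regression with statistical-power-constrained pruning and
   leave-one-out validation.

A synthetic-data module generates full participants (EEG plus trial logs)
with planted connectivity–behavior structure, so every stage is testable
without human recordings.

## Tracing-error scoring

The track is built from eight axis-aligned quarter-ellipses forming four
petals, one per screen quadrant; each petal joins the central vertex to a
petal tip, so the section endpoints are five vertices in total. An
axis-aligned quarter-ellipse cannot join two points of the same axis line,
which is why the petals lie along the quadrant diagonals — the only
construction compatible with eight quarter-ellipse sections, five vertices,
and symmetry about both axes.

The **position error** of a trial is the area enclosed between the traced
polyline and the track section. Both curves are resampled to a common dense
arc-length grid and concatenated (trace forward, track backward) into one
closed polygon; the polygon is split into simple sub-loops at every proper
self-crossing and the absolute sub-loop areas are summed. Splitting prevents
regions on opposite sides of a crossing from cancelling — the quantity is
"how much area lies between the curves", not a signed integral. The tests
check this implementation against an independent even-odd scanline
rasterization oracle at a 0.1-pixel grid (1% agreement over 100 random
smooth perturbations). The two definitions genuinely diverge for extremely
wiggly traces whose sub-loops overlap themselves; such traces do not occur
in mouse trajectories at realistic noise levels.

Scoring parameters (all configurable):

* `pixel_area_cm2 = 0.0025` (0.25 mm² per pixel); endpoint offsets use the
  linear scale `sqrt(0.0025) = 0.05` cm/px, assuming square pixels.
* "Came to rest" is the first sample after which the pointer stays within a
  5-pixel radius of the destination vertex for the 1-second dwell that
  completes a trial; trials that never dwell are flagged incomplete.
* The trial clock starts at the first sample displaced more than 1 pixel
  from the start vertex.
* The endpoint penalty (accumulated per-sample offsets from the destination
  between first arrival and the start of the dwell) is added to the position
  error *before* multiplying by the tracing time; a `penalty_timing = "post"`
  switch adds it after the product instead, since the verbal definition of
  the position–time score admits both readings.

Sessions are summarized either by the median of all trials (single-median)
or by the medians of the first and last 30 trials (dual-median,
distinguishing within-session pre- and post-training skill). Even-count
medians use the midpoint convention. The `sd_ratio()` diagnostic (SD over
median of the first *n* trials) is provided for judging how many trials a
stable estimate needs.

## Connectivity indices

The front end is a zero-phase 1–45 Hz FIR bandpass (Hamming windowed-sinc
applied forward and backward; the order scales as `3.3 * fs / lo`, giving a
transition band below the low cutoff and >50 dB stopband attenuation per
pass). Five canonical bands (Delta 1–4, Theta 4–8, Alpha 8–15, Beta 15–30,
Gamma 30–45 Hz) are each split into three sub-bands. Only four sub-band
centers are fixed by the analysis configuration this package reproduces
(13, 16, 21, 27 Hz); the remaining eleven default to rounded sub-band
midpoints (Delta 1.5/2.5/3.5, Theta 4.5/6/7.5, Alpha 9/11, Gamma 32/37/42)
and can be overridden, subject to each center lying strictly inside its
parent band.

Each center gets a complex Morlet wavelet with 7 cycles (time-domain SD
`cycles/(2*pi*f)`, truncated at ±4 SD, unit energy; spectral FWHM recorded
per wavelet). Seven cycles makes neighboring centers roughly one spectral
bandwidth apart, consistent with the sub-band spacing; cycle counts below 3
are rejected because the phase estimate becomes too broadband to interpret.
Convolution uses reflect padding; the 30-second analysis offset discards
edge transients anyway.

Per 1-second epoch (250 samples, epoch grid anchored at the recording
start), five estimators are computed from the cross-spectrum
`S = x * Conj(y)`:

| metric | definition | range |
|---|---|---|
| phase clustering (PLV) | `abs(mean(exp(1i*dphi)))` | 0–1 |
| PLI | `abs(mean(sign(Im S)))`, `sign(0)=0` | 0–1 |
| wPLI | `abs(mean(Im S)) / mean(abs(Im S))`, `0/0 -> 0` | 0–1 |
| spectral coherence | `abs(mean S)^2 / (mean(abs(x)^2) * mean(abs(y)^2))` | 0–1 |
| imaginary coherence | `abs(Im(mean S)) / sqrt(mean(abs(x)^2) * mean(abs(y)^2))` | 0–1 |

These are per-epoch estimators rather than epoch-averages of sample-wise
quantities; the two coincide for PLV and PLI but differ in the coherence
normalizations, and the per-epoch estimator is the interpretation adopted
here (a single continuous resting recording offers no trials to average
over). The **connectivity index** of a (pair, center) cell is the *maximum*
per-epoch value inside a 120-epoch window starting 30 s into the recording
(out of 300 epochs for a 5-min recording) — peak detection favors transient
synchronization episodes over tonic levels.

## PLS brain–behavior modeling

For one candidate model the design matrix holds one row per session and one
column per electrode pair (one metric, one center frequency, one EEG
condition). Columns are z-scored and the behavior mean-centered;
standardization makes the coefficient-magnitude pruning rule scale-free.

* **PLSC.** With a single behavioral variable the SVD of the z-scored
  cross-correlation degenerates helpfully: the salience vector is the
  unit-normalized correlation profile and the singular value its norm. The
  permutation test shuffles behavior labels (2000 by default) and counts
  `(1 + #{perm >= obs}) / (1 + n_perm)`. Bootstrap resampling of sessions
  (1000 by default) yields per-feature bootstrap ratios
  (salience / bootstrap SE).
* **Consensus.** The bootstrap is repeated 50 times with independent
  streams; features with `|BSR| >= 2` (a ~95% normal interval; configurable)
  in more than 80% of repetitions form the consensus set. At six to eight
  sessions the bootstrap ratio measures *stability*, not significance:
  chance correlations among 496 features reach |r| ≈ 0.9 at n = 8 and
  survive resampling, so the consensus retains some stable noise features
  at any threshold — it is the later pruning stage that removes them. With
  more sessions the statistic separates cleanly (the tests demonstrate
  exact planted-set recovery and empty null consensus at n = 40).
* **PLSR.** Standard PLS1: per component a weight vector from the
  covariance, scores, loadings, rank-one deflation; coefficients are mapped
  back to feature space. `plsr_fit()` defaults to `min(k, n - 2)`
  components; the model search and pruning evaluate with a single latent
  variable, because one behavioral variable with strongly collinear
  consensus channels supports exactly one predictive direction, and at
  n ≤ 8 additional components only amplify leave-one-out variance.
* **Power-constrained pruning.** From the in-sample R², Cohen's
  `f2 = R2/(1-R2)` and the noncentral-F distribution
  (`df1 = k`, `df2 = n-k-1`, noncentrality `f2*n`) give the power of the
  overall F test; while power < 0.8 at alpha 0.05 the channel with the
  smallest absolute standardized coefficient is dropped (ties by column
  order). Channel counts exceeding `n - 2` are pruned unconditionally.
* **Evaluation.** Leave-one-out over sessions (fold-internal
  standardization), RMSE expressed as a percentage of the mean behavior,
  and the slope of the zero-intercept least-squares line of estimated
  versus actual.
* **Search.** The candidate grid is {metric} × {center} × {pre/post EEG} ×
  {single/dual} × {pos/pos-time}. Candidates with permutation p ≥ 0.05 are
  screened out (uncorrected, matching the individualized, exploratory
  setting); the winner minimizes RMSE%, ties broken by fewer channels and
  then smaller p. Each candidate model uses one center frequency; a pooled
  all-frequency design is possible by concatenation but is not the default,
  since per-participant models in this setting pair one band with one
  behavior variant.

## The synthetic participant

`synthetic_design()` fixes the study conditions the generator emulates:
seven sessions (six to eight supported), 32 channels at 250 Hz, 5-minute
recordings, 90 trials per session.

* **Background**: independent 1/f (pink) noise per channel, unit SD.
* **Planted coupling**: each planted electrode pair (default five
  disjoint pairs — T7–CP6, FC1–P4, C4–P3, PZ–OZ, FZ–FC5 — matching the
  largest per-participant channel count the method reports; a sparser
  planting starves the permutation screen, whose norm statistic pools
  all 496 features) receives two
  oscillators at the planted center frequency (default 21 Hz, amplitude 1)
  whose relative phase follows Adler/Kuramoto dynamics — natural detuning
  1.2 Hz, coupling strength proportional to the session's coupling level
  `kappa`, phase diffusion 0.15 rad/sqrt(s), preferred lag π/4 when locked.
  Below the locking threshold the relative phase slips at rate
  `detune * sqrt(1 - kappa^2)`, so the peak-detected PLI rises smoothly and
  monotonically with `kappa`. This mechanism was chosen over a
  jittered hard-locked oscillator after analysis showed that *any*
  sustained locking saturates the peak detector: a 7-cycle wavelet limits
  relative-phase dynamics to a few independent values per 1-s epoch, so
  epochs without a sign flip (per-epoch PLI exactly 1) occur for planted
  and even for pure-noise pairs, and the 120-epoch maximum pins at 1. The
  default coupling range (0.72 down to 0.55 across sessions) spans the
  steep, locally linear part of the measured transfer curve; outside it the
  index either flattens (low `kappa`) or hits the ceiling (`kappa` ≳ 0.8).
  A `zero_lag_common` switch replaces lagged coupling by a zero-lag common
  source — the volume-conduction confound that inflates PLV and spectral
  coherence while PLI, wPLI and imaginary coherence stay near their null
  level.
* **Behavior**: `b = 2 + 8 * kappa + N(0, 0.15)` cm² — tracing error
  decreasing as coupling decreases across sessions, with R² in the planted
  relation matching the high-R² regime the method targets.
* **Trials**: each trial is the section polyline plus smooth correlated
  noise tapered to zero at the vertices, with the noise SD calibrated so
  the expected median position error reproduces the session's behavior
  value (`sigma = target_area / (L * sqrt(2/pi) * 2/pi)`); sections and
  directions are drawn uniformly, timestamps follow a lognormal-jittered
  constant-speed model at 600 px/s, and every trial ends with a ~1.3-s
  dwell at the destination.

What the generator does **not** emulate: eye/muscle artifacts, electrode
impedance drift, volume-conducted background (beyond the explicit confound
switch), cross-frequency structure, or non-stationarity within a recording.
Passing tests therefore demonstrate the correctness and calibration of the
estimators and of the selection machinery under the planted model — not
robustness to real-world EEG contamination.

## Numerical choices and degenerate inputs

* Even-count medians: midpoint of the central order statistics.
* `sign(0) = 0` in PLI; `0/0 -> 0` in wPLI and the coherence
  normalizations; zero-amplitude samples contribute 0 to PLV.
* Zero-variance design columns are dropped with a warning in PLSC; a
  constant behavior vector is an error in PLSC and a mean-only fallback in
  PLSR (leave-one-out RMSE 0).
* Permutation p-values include the observed statistic in numerator and
  denominator, so they are never 0 and are valid (conservative) at any
  permutation count.
* All resampling is driven by explicit seeds; fixed seed means bit-identical
  results, and derived streams (consensus repetitions, search candidates,
  sessions) are offset so they are mutually independent.
* Tie-breaks are deterministic everywhere (first column / first grid row).

## Problem sizes used by the test-suite

The unit and integration tests run the full algorithmic surface at reduced
problem sizes chosen for quick iteration: 60-second recordings with a
10 s + 45-epoch analysis window in the end-to-end test, 60-trial sessions,
and reduced permutation/bootstrap counts (these only coarsen p-value
granularity, which the assertions account for). The acceptance script runs
the connectivity stage at the full 5-minute / 300-epoch / 496-pair scale
and the end-to-end participant at full recording length with the PLI
metric. At the reduced end-to-end scale, spectral leakage between
neighboring Beta sub-band wavelets (FWHM ≈ f/7 · 2.355 ≈ 5–9 Hz) means the
selected center can land on a Beta neighbor of the planted 21 Hz cell; the
test accepts the Beta sub-band triplet while the full-scale acceptance run
reports the selected center directly.

## Known limitations

* The bootstrap-consensus stage cannot, even in principle, reject stable
  chance correlates at n ≤ 8 (see above); interpretation of selected
  channels at study scale should lean on the permutation screen, the power
  constraint, and replication across sessions rather than on the BSR alone.
* The peak-detected index is a maximum of ~120 weakly dependent values and
  is therefore noisy and ceiling-prone; tonic synchronization changes would
  be better served by the epoch mean, which the per-epoch tensors
  (`keep_epochs = TRUE`) expose for custom analyses.
* `regression_power()` uses the fixed-design noncentral-F convention
  (`lambda = f2 * n`) on the in-sample R², which is optimistic at small n;
  it reproduces the published configuration's behavior and is validated
  against Monte-Carlo rejection rates in the tests.
* EDF support covers continuous, equal-rate, 16-bit recordings only.
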