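---
title: "Methods: from pulse waveforms to HRV-coupled connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pulse waveforms to HRV-coupled connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocardiac)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data tests can show. The
package implements a neurocardiac analysis chain: heartbeats and
heart-rate variability (HRV) from a finger-pulse waveform,
physiological-noise cleaning of resting-state BOLD, seed-based and
sliding-window connectivity, and network-based inference on whole-brain
connectomes.

## Beat detection and HRV

A pulse-wave arrival is a steep rise in the optical pulse signal, so the
beat fiducial is the maximum of the first derivative within each
upstroke. Concretely, `detect_pulse_peaks()`:

1. low-pass filters the signal at 10 Hz (zero-phase, 2nd-order
   Butterworth) — differentiation amplifies broadband sensor noise while
   the upstroke itself lives below ~10 Hz;
2. takes local maxima of the first derivative above an adaptive
   threshold, `deriv_threshold_frac` (default 0.4) times the rolling 10-s
   derivative maximum, which makes detection insensitive to slow
   amplitude drift of the sensor;
3. enforces a 300 ms refractory interval (`min_ibi`), keeping the steeper
   of two competing upstrokes — no physiological rhythm at rest beats
   faster than 200 bpm.

The inter-beat-interval (IBI) cleaning rule (`clean_ibi()`) replaces the
study practice of visual inspection with an auditable automated proxy: an
interval is invalid if outside 300–2000 ms or if it deviates more than
30% from an 11-beat running median; invalid intervals are replaced by
linear interpolation between valid neighbours and flagged `corrected`.
Recordings with more than 20% invalid intervals are rejected as unusable
— but only when the series has at least 10 intervals, since a shorter
series cannot support a quality judgement and its one outlier is better
corrected than fatal. Corrected intervals intentionally no longer equal
raw beat-time differences; raw timing is retained so windowed analyses
stay on the acquisition clock.

HRV metrics use a single set of conventions, stated here once: heart rate
is `60000 / mean(IBI)` (not the mean of instantaneous rates), SDNN is the
sample standard deviation (n − 1 denominator, appropriate for a finite
recording), and RMSSD is the root mean square of successive differences.
Breathing rate is the inverse mean interval between respiratory maxima,
which are detected with a minimum prominence of 10% of signal range
(guarding against small superimposed wiggles) and a 1.5 s minimum
separation.

## Physiological-noise model

Two mechanisms couple respiration into the BOLD signal, and the design
addresses each:

- **Cycle-locked artifact.** Respiratory phase is assigned linearly from
  0 to 2π between successive inspiratory maxima (0 at a peak, by
  convention), and expanded into `sin(kφ)`, `cos(kφ)` for k = 1, 2 — four
  low-order Fourier regressors. The linear-phase construction was chosen
  over an amplitude-histogram phase for determinism and testability; it
  depends only on peak times and is therefore invariant to amplitude
  scaling of the trace. Phase is computed volume-wise (not slice-wise).
  Cardiac Fourier terms are deliberately not included; the design models
  respiratory artifact only.
- **Slow vascular response to breathing depth/rate.** Respiration volume
  per time (RVT) is breath amplitude (peak minus adjacent trough) over
  breath period, interpolated from breath-wise values at peak times to
  volume times with constant extrapolation beyond the first/last breath.
  Because the vascular response lags, the design uses the RVT series and
  four delayed copies at 5, 10, 15 and 20 s (edge-padded), five columns
  in all.

Cleaning is sequential: OLS removal of trends (intercept, linear,
quadratic) plus all nuisance regressors first, then band-pass. Residuals
are exactly orthogonal to every retained design column; rank-deficient
designs drop collinear columns with a warning naming them. The band-pass
is a 4th-order Butterworth applied forward-backward (zero phase
distortion), retaining 0.01–0.1 Hz; each series is demeaned before
filtering since the mean is outside the pass band and removing it first
avoids large forward-backward edge transients. Spatial smoothing is a
separable 3-D Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in
voxel units (default FWHM 6 mm), zero-padded at the grid edge with a
normalized kernel, so total intensity is conserved away from edges.

## Seed connectivity and group inference

A seed is the set of voxels whose centers fall within a radius of an MNI
coordinate (inclusive boundary; the NIfTI affine is authoritative for the
voxel/mm mapping). The default seed is a 10 mm sphere at the ventromedial
prefrontal cortex, MNI (0, 44, −14); on a 2.5 mm grid centred on a voxel
this contains 257 voxels. Seed maps correlate the seed-mean series with
every in-mask voxel and apply the Fisher transform `z = atanh(r)`.
Essentially perfect correlations (|r| > 1 − 1e−7) are clamped to
1 − 1e−6 and flagged, keeping the transform invertible over the working
range |z| < 8 while avoiding infinities at self-correlation.

Group tests are voxelwise t-tests: one-sample, paired (implemented
exactly as one-sample on within-subject differences), or two-sample with
pooled variance (the classic convention; Welch by flag). Cluster
correction thresholds voxels at an uncorrected p (default 0.005,
two-sided), labels face-connected (6-connectivity) clusters of
same-signed voxels, and compares each observed extent with the
permutation distribution of the maximum extent — sign flips for
one-sample/paired designs, label shuffles for two-sample — using the
add-one estimate `(1 + #{null >= obs}) / (1 + n_perm)`, which can never
be exactly zero. A cluster-level Benjamini–Hochberg FDR over the cluster
p values is reported alongside the FWE p, covering both correction
conventions a reader may expect; the permutation FWE is the default.

## Sliding-window coupling

Windows are rectangular (no taper), 90 volumes long with a 45-volume
step. Window counts in volumes are authoritative; at TR 0.484 s a window
spans 43.6 s, which the field would describe as "45 s". An interval
belongs to the window containing its closing beat, and windows with fewer
than 10 intervals are flagged missing rather than contributing an
unstable SDNN. The SDNN regressor is z-scored per subject before the
voxelwise OLS slope of windowed z on windowed SDNN is taken, so slopes
are comparable across subjects with different HRV scales (the slope is
invariant to any affine rescaling of the raw regressor); windows missing
on either side are dropped pairwise, and at least 8 usable windows are
required. Group inference on the slope maps reuses the one-sample
cluster machinery above.

## Connectomes and the network-based statistic

Nodes are 5 mm-radius spheres (10 mm diameter) at supplied MNI
coordinates, with a warning if centers come closer than 10 mm (overlap).
Node×node Fisher-z matrices mark edges shorter than 20 mm invalid —
short-range correlations are inflated by spatial smoothing — and edges
invalid in any subject are excluded from the whole analysis
(complete-case). The network-based statistic then:

1. computes a paired (or two-sample) t per valid edge; the default tail
   is T2 > T1;
2. forms connected components from edges with t above the forming
   threshold (default 4.17), via union-find; a component's extent is its
   edge count (the intensity statistic, the sum of `t - threshold` over
   component edges, is available by flag);
3. assigns each observed component `p = (1 + #{permutations whose
   maximum component statistic >= observed}) / (1 + n_perm)`, with
   within-pair sign flips (independent per subject) as the paired
   permutation scheme. For small paired designs all `2^n` sign patterns
   can be enumerated exhaustively.

The forming threshold 4.17 is treated as a plain user parameter (its
default mirrors common practice for a paired design of this size); the
permutation seed is a parameter and is recorded in the result object.

Two calibration facts matter when interpreting NBS output, and the test
suite checks both. First, with a sparse null (few suprathreshold edges)
the maximum *extent* is almost always 0 or 1, so its permutation p values
are heavily tied and super-uniform: family-wise error control is valid
but conservative, with realized false-positive rates well below the
nominal 0.05. The continuous *intensity* statistic breaks these ties and
is calibrated essentially exactly; the suite verifies the intensity
false-positive rate sits inside the 95% binomial interval around 0.05
and the extent rate never exceeds it. Second, edge-level recovery of a
planted effect is bounded by per-edge power: a paired shift of
d × sd(difference) gives noncentrality `d sqrt(n)`; at d = 1.2, n = 15
that is 4.65 against a forming threshold of 4.17, so each affected edge
exceeds threshold with probability ≈ 0.67 and no implementation can
recover a large fraction of such an effect reliably — the suite records
the achieved rate rather than pretending otherwise.

## The synthetic-data generator

Every generator is a deterministic function of a `sim_config()`,
including its mandatory seed, and emits its ground truth (beat times,
extrema times, coupled nodes, effect edges) for exact scoring. Defaults
describe a healthy resting adult under a fast-TR protocol: mean IBI
856 ms (≈ 70 bpm), SDNN 54.4 ms, breathing 16 breaths/min, TR 0.484 s,
physio sampling 100 Hz (tests that probe timing accuracy use 250 Hz,
closer to hardware rates).

- **IBI series**: mean plus respiratory sinus arrhythmia (sinusoid at the
  breathing frequency, 25 ms amplitude), a 0.1 Hz oscillation (the
  Mayer-wave band), and AR(1) noise; the fluctuation is rescaled so the
  realized SDNN matches the target.
- **Pulse waveform**: a fixed asymmetric template per beat whose
  derivative is by construction a narrow Gaussian upstroke at lag zero
  minus an equal-area slow decay, so the maximum first derivative falls
  on the beat time and the waveform returns to baseline.
- **Respiration**: a sinusoid generated through an explicit phase
  integral (with optional slow frequency drift and amplitude jitter), so
  true extrema times are known exactly.
- **HRV-coupled BOLD**: coupled nodes follow
  `x(t) = (a + kappa * S(t)) * s(t) + noise`, where `s` is a latent
  in-band seed signal and `S` the standardized windowed-SDNN envelope
  interpolated to volume times — amplitude modulation of a shared
  signal, the simplest mechanism that makes window-wise correlation
  track HRV. This is a modelling convenience, not a claim about
  physiology. All noise is band-limited to 0.01–0.1 Hz by random-phase
  Fourier synthesis.
- **Paired connectomes**: subject matrices are a shared baseline
  (sd 0.2 in z units) plus a subject random effect (sd 0.05) plus edge
  noise (sd 0.1, session-independent — consistent with the modest
  test–retest reliability of edge estimates); the T2 set adds the
  effect on a planted connected subgraph. The effect size d is the
  paired Cohen's d: the shift equals d times the standard deviation of
  the within-subject difference. Synthetic node coordinates sit on a
  jittered lattice that respects the 10 mm spacing rule, and planted
  trees only use edges that survive the 20 mm distance mask.

What these simulations do *not* emulate: hemodynamic response shape,
scanner noise spectra (drift, spikes, physiological aliasing), head
motion, anatomical variability, or spatial autocorrelation of real BOLD.
Passing tests demonstrate that the estimators and inference machinery are
correct and calibrated under the stated model — not that effect sizes of
real interventions are detectable at these sample sizes.

## Problem sizes and numerical choices

Simulation-based tests use sizes chosen to make their statistical targets
sharp yet quick: 60-node connectomes with 15 pairs for NBS calibration
(200 null cohorts) and recovery (20 cohorts), 30 subjects × 20 nodes ×
~660 volumes for the dynamic-coupling recovery, and ~1000-volume series
for the cleaning chain. Tie-breaks and degenerate inputs are handled
explicitly: constant regressors are flagged and dropped with a warning,
zero-variance voxels yield NA (flagged undefined) rather than errors,
empty cluster/component lists are valid results, and all permutation
p values use the add-one correction. Windows that cannot hold a full 90
volumes are dropped rather than shortened.

## Known limitations

- Beat detection assumes a clean optical pulse; arrhythmia or sensor
  loss beyond ~20% of intervals rejects the recording rather than
  attempting repair.
- The respiratory phase is volume-wise; slice-wise correction is out of
  scope, as are slice-timing correction, realignment, normalization and
  skull-stripping (motion parameters are consumed as a given TSV).
- Cluster inference assumes exchangeability under sign flips or label
  shuffles; it does not model spatial autocorrelation beyond what the
  data carry.
- Frequency-domain and nonlinear HRV, ECG R-peak detection, alternative
  dynamic-connectivity estimators, and graph-theory summaries of the
  connectome are out of scope.
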