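---
title: "Methods: beat-to-beat QT delineation, validation statistics, and the synthetic ECG generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-to-beat QT delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgqt)
```

## The measurement problem

The QT interval — from the onset of ventricular depolarization (QRS onset)
to the end of repolarization (T-wave end) — is the ECG quantity behind
long-QT syndrome diagnosis and drug-safety assessment. Measuring it *per
beat* is hard for two reasons. First, any single lead is a projection of the
cardiac dipole: as the heart axis rotates (posture change, respiration,
inter-subject variation), T-wave amplitude in a given lead can collapse to
nothing. Second, the T-end itself is a soft landmark: the wave returns to
baseline asymptotically, and altered morphologies (broad, notched, biphasic,
low-amplitude T waves) defeat rules tuned to a textbook T.

`ecgqt` addresses both issues by measuring the T end *everywhere* — on all
12 standard leads and on three derived scalar channels that are insensitive
to axis orientation — and fusing the local estimates robustly.

## Processing chain and its assumptions

### Conditioning

Each lead is band-pass filtered (2nd-order Butterworth, 0.5–100 Hz, applied
forward and backward so the phase is zero; the corners are the −3 dB points
of a single pass), notch filtered at the 50 Hz power-line frequency
(2nd-order IIR, −3 dB bandwidth 0.33 Hz), baseline corrected by subtracting
a running median (window equal to 501 samples at 600 Hz, kept at the same
physical duration, 835 ms, for other native rates), and resampled to the
canonical 1000 Hz analysis rate by band-limited polyphase interpolation.
All delineation windows are computed at 1000 Hz, which makes the measurement
nearly independent of the acquisition rate (an invariant the test suite
checks: the same underlying signal rendered at 600 Hz and 1000 Hz yields
per-beat QT differing by at most 2 ms).

Two numerical choices are worth recording:

* The notch biquad is parameterized so that the *digital* response has
  exactly the specified −3 dB bandwidth (`beta = tan(pi * bw / fs)`); the
  more common analog-prototype parameterization shrinks the realized
  bandwidth by several percent at 600 Hz. The notch is applied in a single
  pass — a bidirectional application would square the magnitude response and
  widen the measured −3 dB bandwidth by roughly half.
* IIR start-up transients are tamed by anti-symmetric reflect padding
  (several seconds) rather than by discarding data, so short records remain
  usable end to end.

The running-median baseline estimator assumes that, within any 835 ms
window, at least half the samples are near the isoelectric level. At high
heart rates with long QT intervals this assumption is strained, and the
estimator then bites into the T wave itself; the consequences are discussed
under *Limitations*.

### Scalar channels

The cross-lead RMS and SD channels are built from the nine unipolar traces
only: the six precordial leads and the three reconstructed unipolar limb
leads (2/3·aVR, 2/3·aVL, 2/3·aVF — an exact algebraic identity between the
Goldberger augmented leads and the Wilson-terminal-referenced unipolar
potentials, which the tests verify to machine precision). Using only
unipolar leads gives every electrode equal weight. Both formulas use the
divisor 9 (population form), so the pointwise identity
`sd² + mean² = rms²` holds exactly and is tested at 1e−9 relative
precision. The third scalar channel is the magnitude of the
vectorcardiogram synthesized with the fixed Kors regression matrix; the
magnitude is invariant under rotation of the X/Y/Z triple, which is the
formal sense in which it is heart-axis independent.

### Fiducials

R peaks come from a Pan-Tompkins detector run on the RMS channel (5–15 Hz
band-pass, derivative, squaring, 150 ms moving-window integral, adaptive
dual thresholds, 200 ms refractory, search-back), with each detection
refined to the RMS argmax within ±30 ms. The QRS onset is the largest
*signed* second derivative (central differences) of the RMS channel in the
window 100–20 ms before the R peak: the RMS channel is nonnegative, so the
onset upstroke produces the dominant positive curvature. Ties break toward
the later sample. Beats whose window would leave the record are flagged and
skipped.

### T-wave delineation and fusion

Per channel, on the Savitzky–Golay smoothed trace (order 2, 51 samples at
1000 Hz; the same trace is used for the baseline, for consistency):

* baseline: median amplitude of the 30 ms before the QRS onset (a truncated
  window is accepted down to 10 ms);
* local T peak: the extremum with the largest |amplitude − baseline| in
  [R+50 ms, R+0.7·RR], where RR is the preceding interval (the first beat
  of a record, which has none, is skipped);
* local T end: the maximum-|slope| point *directed from the T extremum
  toward the baseline* in [T_peak, T_peak+0.3·RR], with slope from the
  printed ±5 ms central difference; the tangent through that point is
  intersected with the baseline in continuous time and rounded half-up to a
  sample. Slopes below 1 µV / 10 ms are rejected as flat; crossings beyond
  T_peak + 0.5·RR are rejected as non-crossing.
* the 50 µV rule: standard leads whose measured |T amplitude| is below
  50 µV (strict inequality) are excluded; the scalar channels are exempt,
  so a beat with globally low limb-lead T waves still gets a QT from the
  precordial and scalar channels.

Fusion applies, independently to the local T peaks and T ends of a beat:
values deviating more than twice the standard deviation from the median are
removed in one pass, and the global landmark is the median of the survivors
(even counts: mean of the middle two, rounded half-up). The SD here is the
population SD of the included values about their mean — the standard
reading of "standard deviation"; if it is zero nothing is excluded. The
amplitude rule runs before the outlier rule. A randomized suite cross-checks
this fusion against an independent brute-force enumeration on 10⁴ landmark
sets.

## Validation statistics

The agreement module reproduces the statistics used to validate QT
algorithms against human observers: Pearson correlation with a Fisher-z
95% CI; the two-way mixed absolute-agreement intraclass correlation
(single- and average-measure forms, computed from the package's own
mean-squares decomposition with F-based confidence bounds, and tested to
1e−9 against mean squares obtained independently from `aov`); and
Bland-Altman bias with 1.96·SD limits of agreement. Beat selection for
validation mirrors the stratified design used with supine-standing tests:
one random beat each from below the 10th RR percentile, from the
interquartile range (inclusive), and from above the 90th percentile.
Percentiles use linear interpolation between order statistics (R type 7);
the draw is seeded and deterministic.

## The synthetic generator

Real LQTS recordings cannot ship with a package, so every stage is
exercised on synthetic 12-lead ECGs with *analytic* ground truth. Design
principles:

* **Geometry first.** Each wave (P, QRS, T) is a scalar time course on a
  fixed 3-D axis; leads are projections through a fixed electrode geometry
  in which the limb electrode vectors sum to zero. Einthoven's identity
  II = I + III and the Goldberger relations therefore hold *by
  construction*, to machine precision, even with noise — because noise,
  50 Hz interference and baseline wander are injected at the electrode
  level, not per lead.
* **Truth is the quantity the method estimates.** The T-end ground truth is
  *defined* as the tangent-line intercept of the noiseless generating
  terminal T bump (µ + 2s for a Gaussian limb of width s), not the bump's
  support end, so truth and estimate are commensurable. Likewise the QRS
  onset truth is the analytic curvature maximum of the R bump.
* **Compact support where the ECG is compact.** P and QRS are raised-cosine
  bumps with finite support (QRS: R ± 40 ms). A Gaussian QRS would retain
  ~20% of its peak amplitude at its own curvature-max onset and leak into
  the PQ baseline window; a real PQ segment is isoelectric. The raised
  cosine also places the curvature maximum exactly at the support edge,
  giving a clean analytic onset. T waves are bi-Gaussian (independent left
  and right widths): the left width is capped so the T upstroke stays clear
  of the PQ window, while the right limb remains exactly Gaussian so the
  tangent truth is exact.
* **Morphology presets** encode LQT-like shapes through the terminal-limb
  width s (so that the T-peak-to-T-end interval 2s stays within clinically
  reported ranges) and bump composition: `monophasic` (s = 80 ms),
  `broad` (s = 90 ms, broad-based, normal amplitude, the LQT1-like shape),
  `notched` (two positive bumps 110 ms apart, LQT2-like), `biphasic`
  (negative then positive), and `low_amplitude` (T axis nearly anterior, so
  every limb-lead T amplitude falls below the 50 µV rule while precordial
  leads stay large). Composite presets take their truth from the terminal
  bump's tangent; the earlier bump's tail at the tangent point is below
  0.3% of its amplitude by construction.
* **RR dynamics.** The RR profile steps from a resting level (default
  1000 ms) to a standing level (default 650 ms) with Gaussian beat-to-beat
  jitter (SD 20 ms), the transition relaxing exponentially with a 5 s time
  constant — the pace of the heart-rate response to brisk standing. An
  instantaneous step would make the T-peak search window (0.7 of the
  *previous* RR) overlap the next beat's QRS for the single transition
  beat; that is an artifact of a discontinuity no physiological recording
  contains, so the generator does not produce one.
* **Defaults as study conditions.** Heart axis 42°, T axis 26° (population
  means of the supine-standing cohort the method targets), QRS dipole
  1000 µV, T dipole 400 µV, broadband noise 10 µV RMS per lead, 50 Hz at
  10 µV, wander 50 µV below 0.3 Hz, QT 400 ms (fixed, or Bazett-adapted).
  All randomness flows from one seed; the global RNG stream is left
  untouched.

What the generator does **not** emulate: respiration-coupled amplitude
modulation (a hook exists in the morphology machinery but is off), ectopy
and arrhythmia, electrode motion artifacts, U waves, and intra-beat axis
rotation (each wave has a fixed axis). Passing tests on this generator
therefore demonstrate correctness of the measurement chain under controlled
morphology, axis, rate and noise conditions — not clinical performance on
pathological recordings.

## Problem sizes used by the tests and the acceptance script

The per-morphology recovery tests run ~220 beats per preset (180 s records
at 1000 Hz); the acceptance script's validation study uses 24 five-minute
records at the 600 Hz native rate with three RR-stratified beats selected
per record, mirroring the stratified design of supine-standing validation
studies. The fusion cross-check enumerates 10⁴ random landmark sets.

## Limitations

* **The conditioning chain moves the T end.** The 0.5 Hz high-pass and the
  running-median baseline subtraction each perturb wide, large T waves:
  relative to the pre-filter analytic truth, per-channel T ends on clean
  wide-T records shift on the order of up to ten milliseconds, in a
  direction and magnitude that depend on heart rate and on where the T sits
  in the cycle. Validation studies that compare two readings of the *same
  conditioned signal* (algorithm vs human observers) do not see this term;
  comparisons against pre-filter truth, as in the acceptance script, do.
  This is inherent to the conditioning parameters, which are part of the
  method's definition here.
* **Tangent noise sensitivity scales with 1/slope.** The steepest-slope
  search takes a maximum over a noisy derivative, which biases the slope
  steep and the intercept early; the effect grows as the terminal limb
  flattens (broad or low-amplitude T waves) and is the reason low-amplitude
  leads are excluded by the 50 µV rule rather than down-weighted.
* **No beat classification.** Ectopic or aberrant beats are not recognized;
  in the intended workflow they are excluded by visual inspection, aided by
  the per-channel QC dump (`qt_pipeline(..., qc = TRUE)` or the CLI's
  `--qc-dump`).
* **Baseline definition.** The PQ-segment baseline is used because the T(U)-P
  segment vanishes at high heart rates; at very high rates the P wave can
  still encroach on the 30 ms window.
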