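---
title: "Detecting postural transitions from a single lower-back IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting postural transitions from a single lower-back IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Sit-to-stand (SiSt) and stand-to-sit (StSi) movements — postural
transitions, PTs — are clinically informative digital mobility markers in
Parkinson's disease and aging. `ptkit` detects, delimits, classifies and
times these transitions from the tri-axial accelerometer and gyroscope of
a single inertial sensor fixed to the lower back, sampled at 128
samples/s, with the sensor's x axis vertical (cranial), y medio-lateral
and z anterior–posterior. This vignette is the package's account of the
method, its tunable parameters, the synthetic data it is validated on,
and its known limitations.

## The processing pipeline

```{r}
library(ptkit)
sim <- default_benchmark(seed = 1)
det <- pt_detect(sim$recording)
det
```

### Preprocessing

The accelerometer is filtered with a 4th-order Butterworth low-pass at
`cutoff_hz = 5` Hz applied forward and backward (zero phase, effective
8th-order magnitude, unit DC gain); human movement lives below ~5 Hz and
everything above is electronic noise. Edges are handled by odd-reflective
padding of 1 s with steady-state filter initialization, so a constant
input passes through unchanged up to the first sample. The gyroscope is
deliberately not low-pass filtered; its only conditioning is bias
removal.

From the filtered acceleration magnitude and the raw angular-velocity
magnitude the pipeline computes trailing-window means and variances over
`window = 128` samples (1 s). The variance is the *per-lag-mean* form —
each lagged sample is compared with the trailing mean at its own lag —
which is not the same as a fixed-mean windowed variance; the two differ
on ramps, and the per-lag form keeps memory of an excursion for up to two
window lengths. The first 127 samples use the partial prefix and are
flagged as warm-up; stationarity decisions and bias latching ignore them
(a one-sample window has zero variance by construction, which would
otherwise latch the bias at the very first sample).

The gyroscope bias latches to the instantaneous gyroscope sample whenever
the variance of the angular-velocity magnitude falls below
`bias_var_threshold = 1e-5` rad²/s², and holds its previous value
otherwise. Two consequences of this latch rule are worth knowing:

* it can only ever fire if the sensor's rest-noise variance floor is
  below the threshold (about 3 mrad/s noise std); with noisier gyros the
  bias is simply never removed, and
* variance cannot distinguish a constant non-zero rate from rest, so a
  perfectly steady rotation would be absorbed into the "bias". Real
  movement is never that steady; the degeneracy matters only for
  idealized synthetic inputs.

### Stationary periods

A sample is stationary (`sp`) when all three hold: the filtered
acceleration magnitude is within `accel_dev_thresh = 0.05` m/s² of
standard gravity (`g0 = 9.81` m/s²), the acceleration-magnitude variance
is below `accel_var_thresh = 0.01` m²/s⁴, and the gyroscope-magnitude
variance is below `gyro_var_thresh = 0.01` rad²/s². Stationary runs
shorter than `min_sp_s = 0.25` s are merged into the surrounding active
period to suppress flicker anchors. Each interior active (`ap`) segment
is bracketed by `n_ls`, the last stationary sample before it, and
`n_rs`, the first stationary sample after it; these anchors drive every
drift correction. Because the statistics windows trail, the `n_rs` anchor
clears roughly 1–2 s after movement actually ends.

### Tilt and wavelet denoising

During `sp` the accelerometer sees only gravity, so the sagittal tilt is
`theta = atan2(a_z, a_x)`, wrapped to `[0, 2*pi)` by adding `2*pi` when
`a_z < 0`. With this mounting, forward flexion dips the anterior axis
below the horizontal, so flexion reads as *negative* tilt (equivalently,
angles just below `2*pi`); that sign convention is what places the
negative-slope zero crossings of the medio-lateral rate at the start and
end of a flexion–extension episode.

During `ap` the medio-lateral angular velocity is integrated (forward
rectangle rule at `1/f_s`) from the tilt at `n_ls`; the accumulated
gyroscope drift is removed by subtracting the linear ramp that makes the
integrated tilt meet the accelerometer-derived tilt at `n_rs`. The
corrected tilt is anchor-exact at both ends. Two numerical choices: the
integral is left unwrapped inside the segment, and the right-anchor
target is taken modulo `2*pi` nearest to the drifting estimate, so a wrap
of the stationary tilt cannot inject an artificial `2*pi` ramp into the
drift slope.

The sine of the tilt (bounded in [-1, 1]) is then decomposed with an
orthonormal Coiflet-5 filter bank, periodized, after symmetric extension
to the next multiple of `2^10` samples. Approximation-only
reconstructions after `j_lo = 3` and `j_hi = 10` levels retain roughly
the 0–8 Hz and 0–0.0625 Hz bands at 128 samples/s; their difference,
`tilt_denoise = R3 - R10`, keeps the transition band while removing both
residual drift and the static posture baseline. The filter bank is exact:
reconstructing with approximation *and* detail reproduces the input to
1e-8, which is the in-package oracle for the implementation.

### Event detection and classification

Candidate events are local extrema of `tilt_denoise` — on both
polarities, since the sagittal sign depends on mounting — whose absolute
height and topographic prominence both exceed `0.1`. Candidates closer
than `merge_window_s = 1` s keep only the strongest; after boundary
location, events whose spans overlap by more than half of the shorter
span are collapsed to the strongest candidate, because reconstruction
ripple can raise a side lobe more than 1 s from the main peak over the
same physical movement.

The start of a transition is the nearest zero crossing of the unbiased
medio-lateral rate left of the peak with negative local slope (the last
non-negative sample of a `+ -> -` sign change); the end is the nearest
such crossing at or right of the peak. Searches are capped at
`max_search_s = 5` s; on failure the enclosing segment's stationary
anchor is used and the event flagged. Durations beyond
`max_duration_s = 10` s are flagged rather than dropped.

Orientation is tracked as a scalar-first unit quaternion: pure gyroscope
strapdown integration during `ap` (`beta_ap = 0`), steered toward the
accelerometer's gravity direction during `sp` with gain `beta_sp = 0.5`
via the feedback rate `cross(a_hat, g_est)`. The cross-product order is
fixed by the fixed-point requirement that a still, aligned sensor stays
put; the opposite sign diverges (tested). The initial quaternion
`q0 = (1, 0, -1, 0)/sqrt(2)` maps the sensor's vertical x axis to the
earth's z axis and is applied at the first stationary sample; samples
before it carry no orientation and events there are detection-only.
Accelerations are normalized by `g0`, conjugated into the earth frame,
and the constant `[0, 0, 1]` is subtracted; the remainder, rescaled to
m/s², is double-integrated per bracketed `ap` segment with the same
anchor-based linear drift removal as the tilt (velocity exactly zero at
both anchors), giving the vertical displacement `d_z`, frozen during
`sp`.

An event is an *effective* transition when `|delta d_z| >= 0.1` m between
its boundaries, SiSt for positive and StSi for negative displacement;
smaller displacements (e.g. forward leans) are *attempts* and are
excluded from validation. `delta d_z` is taken boundary-to-boundary, not
between displacement extremes.

## The synthetic benchmark

Every stage is testable without recorded data through a generator that
emulates a home-like protocol. The trunk is a single rigid segment
rotating about the medio-lateral axis. A transition of duration `T = 2` s
contributes a flexion bump `-0.7 * sin^2(pi (t - t0)/T)` rad and a
quintic-smoothstep vertical step of ±0.25 m (C², so the accelerometer
contains no jumps); leans reuse the bump with zero rise; dyskinesia adds
band-limited 0.5–3 Hz angular noise on all axes; white sensor noise is
0.05 m/s² (accelerometer) and 0.01 rad/s (gyroscope) per axis, with a
constant gyroscope bias (0.01, 0.02, -0.01) rad/s. The default session is
10 minutes: 10 SiSt, 10 StSi and 10 leans at 20 s spacing.

One discretization choice matters: the generator emits *per-step average*
rates — forward differences of the sampled latent trajectory — rather
than instantaneous derivatives. That makes the forward rectangle-rule
integration chain sample-exact, so generator self-consistency holds to
machine precision and time-reversing a session flips the sign of
`delta d_z` without bias. With instantaneous rates the half-sample lag of
rectangle integration would leak ~0.03 m of gravity into every
displacement estimate; the same lag exists on real data, where it is
indistinguishable from sensor imperfections.

The dyskinesia variant places one sustained block over the first half of
the session (0–305 s) at 0.25 rad/s per axis. The amplitude is chosen so
the gyroscope-magnitude variance (~0.45 sigma² ≈ 0.028 rad²/s²) clearly
exceeds the 0.01 stationarity threshold: no stationary period can be
detected for the whole block — continuous involuntary movement is
precisely the mechanism that breaks this algorithm — while the induced
trunk wobble stays near a degree. Starting the block at the session start
also exercises the rule that no kinematics exist before the first
stationary period.

What the generator does *not* emulate: multi-segment biomechanics,
walking, turning-in-bed and other activities that produce false positives
in real life; sensor mounting errors; temperature-dependent bias drift;
out-of-camera exclusions of a video reference. Passing the synthetic
benchmark therefore demonstrates correctness of the signal-processing
chain under its own assumptions, not field performance.

## Evaluation

Detected effective events are matched to reference annotations greedily
by ascending midpoint distance within `tolerance_s = 2` s (the video
references this method is validated against are timed in full seconds,
and transitions last about 2 s, so sub-second matching would be spurious
precision). Matched pairs are true positives; sensitivity is
`100 TP/(TP+FN)`, positive predictive value `100 TP/(TP+FP)`, accuracy
`100 TP/(TP+FP+FN)`. Duration agreement reports the mean and SD of
algorithm-minus-reference durations with `mean ± 1.96 SD` limits of
agreement, plus a Welch t test when two groups are compared.

```{r}
ev <- pt_evaluate(det, sim$truth$annotation)
ev
```

## Known limitations

* **Bias removal can be inert.** With the published latch threshold
  (1e-5 rad²/s²) and a gyroscope noise floor of 0.01 rad/s — the
  benchmark's sensor model — the variance never reaches the threshold,
  the constant bias is never removed, and the end-boundary zero crossing
  (which waits for the biased rate to dip below zero) is delayed by
  ~0.3 s on average. Detection counts, directions and displacements are
  essentially unaffected; durations inflate one-sidedly, in the same
  direction as the positive algorithm-minus-video duration difference
  reported for the original validation. Quieter gyroscopes (noise below
  ~3 mrad/s) restore the latch and remove the inflation; so would
  recalibrating `bias_var_threshold` to the sensor's rest floor, which is
  exactly how the published value was chosen for its own hardware.
* **Boundary flickers.** The single-pair zero-crossing definition can be
  truncated by a noise flicker in the near-zero rate region around the
  tilt peak (~2% of events), producing an occasional short duration. No
  hysteresis is added, to keep the printed rule.
* **Constant-rate degeneracy.** Variance-based stationarity cannot
  distinguish a perfectly constant rotation from rest; such inputs are
  labeled stationary and their rate absorbed as bias. This is inherent to
  the rule, not to this implementation.
* **Accuracy denominator.** The accuracy `TP/(TP+FP+FN)` reproduces only
  one of the four published validation rows exactly; the published
  accuracy column was likely computed with a different denominator, which
  is why sensitivity and PPV (which reproduce exactly for all rows) carry
  the validation burden here.
* **No magnetometer, no barometer, no dyskinesia removal, and no PT
  parameters beyond duration, displacement and direction.**

## Problem sizes

The shipped tests run the full pipeline on 10-minute, 128 samples/s
sessions (76,801 samples): ten seeds of the clean benchmark and six of
the dyskinesia variant, plus shorter fixtures for unit oracles; a session
takes a few seconds end to end. `scripts/acceptance.R` recomputes the
same quantities from scratch in under a minute.
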