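# ptkit

Detection, delimitation, classification and timing of **postural
transitions** — sit-to-stand (SiSt) and stand-to-sit (StSi) movements —
from a single inertial measurement unit (IMU) worn on the lower back.

Postural transitions are among the most informative digital mobility
markers in Parkinson's disease and aging: how often a person stands up,
how long it takes, and whether attempts fail. Counting them reliably
from one 6-axis sensor (3D accelerometer ±16 g, 3D gyroscope
±2,000 °/s, 128 samples/s, no magnetometer) in unscripted, home-like
conditions is the problem this package addresses. It is aimed at
movement-analysis researchers and engineers who need a transparent,
fully testable reference implementation of the whole chain, from raw
CSV streams to event-level validation statistics.

## The algorithm

With the sensor mounted x-vertical, y-medio-lateral, z-anterior:

1. **Preprocessing.** Zero-phase 4th-order Butterworth low-pass
   (f_c = 5 Hz) on the accelerometer; trailing 1-s mean and variance of
   |a| and |ω|; gyroscope bias b_ω latched to ω whenever
   σ²_ω < 10⁻⁵ rad²/s², removed as ω̃ = ω − b_ω.
2. **Stationary periods (sp).** A sample is stationary when
   ||a| − g₀| < 0.05 m/s², σ²_a < 0.01 m²/s⁴ and σ²_ω < 0.01 rad²/s².
   Stationary anchors n_ls, n_rs bracket each active period.
3. **Tilt.** At rest, θ = atan2(a_z, a_x) (+2π when a_z < 0); during
   movement, θ integrates ω_y from the left anchor, with the linear
   drift removed so θ meets the accelerometer tilt at both anchors.
4. **Wavelet denoising.** sin θ is decomposed with Coiflet-5 filters;
   the difference of approximation-only reconstructions after 3 and 10
   levels, `tilt_denoise = R3[sinθ] − R10[sinθ]`, isolates the
   transition band.
5. **Events.** Peaks of |tilt_denoise| with height and prominence
   > 0.1 mark candidate transitions; start/end are the nearest zero
   crossings of ω_y with negative slope on each side of the peak.
6. **Vertical displacement.** A 6DOF quaternion filter (gyro strapdown
   steered toward gravity during sp, β = 0.5; β = 0 during movement)
   rotates a/g₀ to the earth frame; gravity [0 0 1] is subtracted and
   the remainder double-integrated with anchor-based drift removal to
   d_z. Events with |Δd_z| ≥ 0.1 m are effective transitions — SiSt if
   Δd_z > 0, StSi if Δd_z < 0 — the rest are attempts (e.g. forward
   leans) and are excluded.
7. **Validation.** Detected events are matched to reference annotations
   (±2 s on midpoints); sensitivity, PPV, accuracy, direction accuracy
   and duration agreement (mean difference ± 1.96 SD) are reported.

A synthetic session generator with exact ground truth (trunk
flexion–extension bumps, smooth vertical steps, leans, sustained
dyskinesia-like angular noise, gyro bias, sensor noise) makes every
stage testable without any recorded data.

## Worked example

```r
library(ptkit)

sim <- default_benchmark(seed = 1)   # 10 min: 10 SiSt, 10 StSi, 10 leans
det <- pt_detect(sim$recording)
det
#> Postural transition detection
#>   candidate peaks : 42
#>   effective PTs   : 20 ( 10 SiSt / 10 StSi )
#>   attempts        : 22

head(det$effective[, c("start_s", "end_s", "duration", "delta_dz", "direction")], 3)
#>   start_s    end_s duration   delta_dz direction
#> 1      10 12.06250 2.062500  0.2948250      SiSt
#> 2      50 52.02344 2.023438 -0.2158305      StSi
#> 3      70 72.49219 2.492188  0.3036865      SiSt

pt_evaluate(det, sim$truth$annotation)
#> Postural transition evaluation (tolerance 2 s)
#>   TP 20  FP 0  FN 0
#>   sensitivity: 100%  PPV: 100%  accuracy: 100%
#>   direction accuracy: 100%
#>   duration: alg 2.27 (0.30) s, diff 0.27 s, 95% LoA [-0.32, 0.87]
```

All 20 scheduled transitions are recovered with the correct direction;
the 10 forward leans (flexion without displacement) are classified as
attempts and excluded; the recovered displacements (±0.22–0.30 m)
bracket the simulated 0.25 m rise; durations run ~0.3 s long because the
specified sensor noise keeps the bias latch dormant (see the methods
vignette, "Known limitations").

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/ptkit.R simulate --seed 42 --out session.csv --truth truth.csv
Rscript inst/cli/ptkit.R detect   --input session.csv --output events.csv
Rscript inst/cli/ptkit.R evaluate --events events.csv --reference truth.csv --report report.json
```

## Documentation

The methods vignette (`vignettes/pt-detection-methods.Rmd`) documents
the model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices, and known limitations.
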