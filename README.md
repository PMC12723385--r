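# struggleR

Analysis machinery for studying how *Xenopus laevis* tadpoles (stage 37/38)
struggle free from a grip. When a predator seizes a tadpole's head, the
animal produces a stereotyped sequence of movements — an initial coiling,
vigorous struggling, transitional coiling after release, then swimming —
driven by correspondingly distinct motoneuron burst patterns. This package
implements, as tested reusable code, the quantitative machinery such a
study needs:

* **Kinematics** — from 11 pose-tracked midline points, the nine signed
  body-curvature angles
  θ = cos⁻¹(a⃗·b⃗ / |a⃗||b⃗|) (signed by turn orientation), the
  sum-of-angles trace that summarises body shape (≈ ±2π: coiled C/O shape;
  ≈ ±π: struggling S shape; ≤ ±0.5π: swimming), half-cycle segmentation,
  rule-based movement classification, propagation speed from the
  regression of vertex distance on cross-correlation lag, and detection of
  the curvature origin of bidirectional struggling waves.
* **Motor rhythms** — ventral-root-like trace preprocessing (artifact
  truncation, rectification, iterated moving-average smoothing), event
  triggering at k·SD above baseline, burst grouping with duty-cycle and
  period statistics, the rhythmicity index
  R = (peak − trough)/(peak + trough) of the inter-event-interval
  histogram, two-channel cross-correlation propagation, and spike-phase
  calibration with the standard delay 0.185 − 0.00225 × period over
  1.65 mm.
* **Surrogate commands** — a 311-motoneuron-per-side roster (248 rostral
  of 3 mm plus a caudal extension at 4→2 cells per 100 µm), empirical-CDF
  inversion for spike counts and inter-spike intervals (intervals > 13 ms
  excluded), and generators for struggling (4 Hz, caudorostral ≈ +40 mm/s,
  anti-phase sides), swimming (20 Hz, one spike per cycle, ≈ −130 mm/s),
  their reversed variants, and 15-spike initial-coil bursts.
* **Mechanics** — the grip model (contact area A = 1.35Δw − 0.0043 mm²,
  Hooke friction 2μE·A(Δw)·Δw = 151.2Δw² − 0.48Δw µN, fitted friction
  49Δw² + 19.8Δw µN, μ = tan α from the slide angle), elliptical
  body-section areas, Reynolds number ρvL/μ, per-section pressure drag
  ζ·A_proj·ρv²/2, mass × acceleration from tracked motion, and the lever
  escape model F2 = F1·L1/L2, F2x = F2·cos α.
* **Synthetic data** — traveling-wave midline and bursty-trace generators
  with attached ground truth, so every analysis closes the loop against
  known parameters without any external data.

## Worked example

Generate a synthetic struggling movement, analyze it, and classify it:

```r
library(struggleR)

body <- make_tracked_movement(wave_spec("struggling", noise_sd = 0.005))
angles <- lowpass_sum(compute_curvature_angles(body))   # 50 Hz zero-phase
half_cycles <- detect_half_cycles(angles)
prop <- propagation_speed(angles)
classify_movement(half_cycles, prop)
```

```
$label
[1] "struggling"

$amplitude
[1] 2.4

$half_cycle_ms
[1] 125
```

The propagation estimate prints

```
<propagation> 43.2 mm/s (caudorostral), p = 2.39e-14, n = 9
```

i.e. the imposed 42.5 mm/s tail-to-head wave is recovered within 2%, the
125 ms half-cycles match the 4 Hz rhythm, and the 2.4 rad sum-of-angles
amplitude lands in the struggling band. The same loop on a swimming preset
returns `swimming` with ≈ −156 mm/s (head-to-tail) and 25 ms half-cycles.

The numbered scripts under `analysis/` run the full narrative — synthetic
inputs (`01`), kinematics (`02`), rhythm statistics (`03`), surrogate
commands analyzed with the rhythm machinery (`04`), and the closed-form
mechanics (`05`) — writing their tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

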