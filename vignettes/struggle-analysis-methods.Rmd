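---
title: "Methods: kinematics, rhythms, surrogate commands and escape mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematics, rhythms, surrogate commands and escape mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(struggleR)
```

This vignette is the package's own account of its models and the choices
behind them. struggleR quantifies how a gripped *Xenopus* tadpole struggles
free: body-shape kinematics from pose-tracked midlines, burst statistics of
ventral-root-like motor rhythms, statistically matched surrogate motoneuron
commands, and closed-form grip/drag/lever mechanics.

## Midline kinematics

A tracked body is 11 ordered points, head to tail tip, assumed equidistant
(vertex positions 0.1–0.9 of body length; real tracked spacing varies, but
equidistance keeps propagation distances well defined). At each interior
point, with $\vec a$ from the previous point to the vertex and $\vec b$
from the vertex to the next point, the curvature angle has magnitude
$\theta = \cos^{-1}(\vec a \cdot \vec b / |\vec a||\vec b|)$. The arccos is
unsigned, yet alternating bends need bipolar traces, so the implementation
signs the angle by the orientation of the turn in the tracking plane (the
z component of $\vec a \times \vec b$; left bends positive); the magnitude
equals the arccos value to 1e-9 rad, which the suite asserts on random
triples. Coincident consecutive points make the angle undefined: the frame
is flagged missing, never silently zeroed. Short tracking gaps (up to 3
frames, e.g. masked low-likelihood points) are bridged linearly; longer
gaps stay missing and are excluded from regressions.

The sum of the nine angles summarises body shape: near $\pm 2\pi$ an
almost circular C/O coil, near $\pm\pi$ a struggling S shape, within
$\pm 0.5\pi$ a swimming S shape. Angle traces are low-pass filtered at
50 Hz (tunable) with a zero-phase 4th-order Butterworth; zero phase
matters because any filter lag would bias the cross-correlation lags that
propagation speeds are built on. The `signal` filter has no special
initial-condition handling, so traces are mirror-padded before
forward-backward filtering; without padding the edge transients of a
constant trace reach 0.3 of its value.

Half cycles (one bend to one side) are bounded by zero crossings of the
mean-subtracted sum trace, each containing one extremum; amplitude is half
the difference between adjacent opposite extrema. Whether the original
measurements used crossing-to-crossing or extremum-to-extremum bounds is
not derivable from the trace definition alone; crossings were chosen
because they are insensitive to amplitude asymmetry, and for a sinusoid
both conventions coincide (A·sin(2π·7t) gives 71.4 ms and amplitude A,
asserted in the suite). Extrema below 0.1 of the largest excursion are
treated as noise wiggles and discarded.

Movement classification is rule-based on the mean amplitude, the
propagation direction and the release marker: coiling at ≥ 3.2 rad
(initial before release, transitional after), struggling at 1.2–3.2 rad
with tail-to-head propagation, swimming at ≤ 1.2 rad with head-to-tail
propagation. The thresholds sit between the class means observed for the
four movement types (4.1, 2.4 and ≈1 rad) and are configurable; anything
off the rules returns `unclassified` with distances to each class band.

Propagation speed follows the regression construction: cross-correlate
every angle with a reference angle (α4 by default — mid-body angles show
the clearest rhythms), take each correlation peak nearest zero lag, and
regress vertex distance on lag; the slope is the speed, signed positive
for caudorostral (tail-to-head) propagation. Estimates with regression
p ≥ 0.05 are reported as synchronous/unreliable with no finite speed.
Two numerical choices matter at 240 fps, where one sample is 4.2 ms:

* the peak "close to zero" is searched within ±0.6 of the dominant cycle
  period (from the autocorrelation of the reference), and among local
  maxima only genuine lobes count — the global maximum plus near-maximal
  peaks separated from it by a dip below half its height. Noise ripples on
  the main lobe otherwise masquerade as a nearer-zero peak;
* the integer-lag peak is refined by three-point parabolic interpolation,
  without which fast waves (150–250 mm/s, inter-vertex delays of 2–3 ms)
  are unrecoverable.

Because lag noise enters the regression as predictor noise, low
signal-to-noise dilutes the slope toward zero; the recovery suite
therefore runs at coordinate SNR ≥ 10 and recovers speeds of 20–250 mm/s,
both signs, within 5%.

The curvature origin of struggling (bends starting around two-thirds of
body length and propagating both ways) is found by fitting, for every
candidate split vertex, separate lag-versus-position lines rostral and
caudal of the split, requiring opposite slopes, and minimising the pooled
residual; the origin is the intersection of the two lines, and each
branch's speed is the negated inverse slope. A branch whose regression is
not significant is reported as "no propagation detected" on that side, and
a wave with no interior divergence comes back flagged unidirectional.

Yaw is the peak-to-peak excursion of the unwrapped heading of the head
segment (p1→p2) within a cycle window, in degrees.

## Motor rhythm statistics

Traces are preprocessed in the recorded order of operations: declared
stimulus-artifact windows truncated to 0 µV (windows are inputs, not
inferred), full-wave rectification, then a centred moving average of
2.5 ms applied 4 times (the iterated boxcar approaches a Gaussian; the
suite checks the impulse response against direct convolution and that
interior signal mass is preserved to 1e-12).

Events are upward crossings of a threshold k·SD (default k = 5) measured
from a baseline window free of bursts. Two details are implementation
decisions: the threshold is referenced to the baseline *mean*, because a
rectified trace has a nonzero noise floor that a threshold-from-zero would
sit under; and a 1 ms refractory period prevents double triggering on the
two phases of one extracellular potential.

Bursts are events closer than a merge gap, 15 ms by default — just above
the 13 ms bound used to separate within-burst from between-burst
inter-spike intervals. Burst duration is last minus first event; cycle
period the interval between burst starts; duty cycle the ratio of their
means.

The rhythmicity index histograms consecutive inter-event intervals
(default 5 ms bins, 3-bin moving-average smoothing — the original
histograms were read visually, so both are explicit parameters reported
with the result), finds the first trough after the initial peak and the
first following peak, and returns R = (peak − trough)/(peak + trough).
Perfectly periodic trains give R = 1 (the leading empty region serves as
the trough when all mass sits in one mode); a Poisson train's monotone
histogram gives R ≈ 0.05 across seeds; unimodal histograms with no
interior structure return R = 0 flagged. Stray single intervals would
otherwise form spurious "peaks", so later peaks below a quarter of the
tallest later peak are ignored.

Two-channel propagation uses the same windowed peak-nearest-zero
cross-correlation; the delay is reported anatomically (rostral minus
caudal time, positive when the caudal channel leads) so the result is
independent of argument order, and speed is electrode separation over
delay, positive caudorostral.

Spike phases within struggling cycles are calibrated with the standard
delay 0.185 − 0.00225 × period over 1.65 mm, scaled by the actual
separation, adding 0.5 for contralateral recordings, wrapped to
(−0.5, 0.5] with the boundary mapped to +0.5. The calibration's period
unit is taken as seconds: in milliseconds the expression is negative at
every observed struggling period (~250 ms), which cannot be a phase
advance of that size.

## Surrogate motoneuron commands

The roster places 311 motoneurons per side over 0.5–4.8 mm from the
mid/hindbrain border: the 248 cells known rostral of 3.0 mm plus a caudal
extension at a density falling from 4 to 2 cells per 100 µm. Only those
totals and the density rule are published, so the packaged per-bin table
is a synthetic digitization pinned to them (its file says so); positions
spread deterministically within each 100 µm bin.

Spike counts and inter-spike intervals are drawn by inverse transform from
linearly interpolated empirical CDFs. The recorded interval samples are
not deposited, so the default source is a parametric stand-in — log-normal,
median 5 ms, truncated to (0, 13] ms, one per rostral/caudal region —
swappable for user samples; the generator's distribution-matching is what
is tested (two-sample KS distance below the 1% critical value in ≥ 95% of
seeds, rank tests between generated and source intervals), not the
stand-in itself. Spike counts per burst follow a discretized normal with
position-interpolated mean 6.1 → 1.9 and SD 4.1 → 0.9, truncated at ≥ 1:
recorded caudal motoneurons fire as few as 1–3 spikes per cycle, so no
minimum of 2 is imposed there (a minimum of 2 is only implicit in interval
sampling, which needs N ≥ 2).

The struggling command runs at 4 Hz with sides in anti-phase, caudorostral
propagation at +40 mm/s, and a duty-cycle profile rising linearly from
0.40 at 0.5 mm to 0.60 at 4.8 mm (an increasing trend is documented; the
endpoints are this package's choice and configurable). The duty profile is
a property of the *population* burst at a position — single neurons fire
short interval-driven bursts scattered within the population window — so
each neuron's burst is placed uniformly within the local duty window.
Propagation timing is applied to burst centres, not onsets: the duty
window widens caudally, and any onset-anchored placement would add a
position-dependent mean shift that biases onset-versus-position
regressions (a ~50% speed error at the defaults). With centre anchoring,
regressing per-cycle burst centres on position recovers +40 mm/s within a
few percent, and pooled position windows recover the duty profile.
Swimming is 20 Hz, one spike per neuron per cycle, −130 mm/s. Reverse
variants regenerate with the speed sign flipped under the same seed, so
each neuron keeps an identical spike multiset with the delay map negated
and reversal is an exact involution. Initial-coil commands fire one
15-spike burst per neuron on the side opposite to stimulation with ≤ 1 ms
onset spread. A single integer seed controls all draws in a fixed order
(side, then position, then cycle), and the global RNG state is left
untouched.

## Escape mechanics

All grip formulas take the head compression Δw as a fraction of head width
(0.83 mm). Contact area A(Δw) = 1.35Δw − 0.0043 mm² and both friction laws
are clamped at zero below their small positive roots (the models are
meaningless at vanishing compression). The Hooke-law friction
2μE·A(Δw)·Δw expands at the defaults (μ = 0.08 from the 4.5° slide angle,
E = 700 Pa) to 151.2Δw² − 0.48Δw µN; the empirically fitted law is
49Δw² + 19.8Δw µN. The two agree only loosely (ratio 0.6–1.2 over
Δw ∈ [0.1, 0.25]) — they are stated to be comparable with discrepancies,
and both are exposed; the fitted law is used for escape thresholds.

The side-view body is an ellipse with a = body length/2 = 2.5 mm and b
set so the area is 4.95 mm²; section areas are exact elliptical-slab
integrals (additive to 1e-12, symmetric, and matching the five published
rostral-half values within 10% — the original semi-axes are not printed,
hence the tolerance). Pressure drag per section is ζ·A_proj·ρv²/2
(ζ = 1.18) directed against the section's centre velocity (mean of its
end-point velocities). The projected area is A·sin of the angle between
the section axis and the velocity — equivalently the cosine of the angle
to the section normal: the full side area is presented in broadside
motion. Stated as "cosine of the acute angle between section and
velocity", that phrase read literally would zero the drag exactly where
the model is declared valid (perpendicular motion), so the
broadside-consistent reading is implemented and near-axial frames are
flagged low-validity. Mass × acceleration uses central second differences
of section mass centres (optionally after a 50 Hz low-pass; the original
differentiation scheme is unstated), with default masses proportional to
section areas normalised to a 141.41 mg body. The lever model is algebra:
F2 = F1·L1/L2, F2x = F2·cos α, escape when F2x exceeds the grip friction;
the fulcrum position and moving-segment set defining F1, L1, L2 are user
inputs, as they were approximated by eye in the source material.

## Synthetic data: what it does and does not emulate

`make_tracked_movement` imposes a curvature wave
α_i(t) = a·sin(2πf(t − τ(s_i))) with a unidirectional or bidirectional
(origin-diverging) delay map, integrates coordinates by exact per-segment
rotations (so coils with |sum| near 2π are representable), and adds i.i.d.
Gaussian coordinate noise. The per-vertex amplitude is scaled so the *sum*
trace hits the requested amplitude, compensating the attenuation of
summing phase-shifted sinusoids. Presets centre on the observed class
parameters (struggling 4 Hz/2.4 rad/+42.5 mm/s; swimming
20 Hz/1 rad/−156 mm/s; coiling 4.1 rad, near-synchronous).

`make_vr_traces` emits biphasic spike waveforms in bursts with
position-dependent onset delays, optional onset jitter, per-event dropout
and a sporadic background whose rate grows with electrode position, plus
Gaussian noise; ground-truth event times ride along. Dropout alone cannot
lower the histogram rhythmicity index — it thins the peaks but leaves the
inter-peak trough empty — so the documented caudal decline in rhythmicity
is emulated by the sporadic component, which genuinely fills the trough.

These generators are kinematic and statistical, not dynamical: midlines
ignore hydrodynamics, trace noise is white, and real tracking errors are
neither Gaussian nor independent. Passing the closed-loop suites therefore
demonstrates that the analysis recovers known parameters under the stated
noise models, not that it is robust to every pathology of real video or
extracellular data.

## Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen as the smallest
that leave comfortable statistical margin: 1.5–3 s of 240 fps tracking per
movement, 10–40 cycle trace simulations at 10 kHz, 8-cycle commands over
the full 622-neuron roster, 10-seed replicates for stochastic properties,
and 100-seed replicates only for the cheap KS check. Every stochastic path
takes an explicit integer seed; same seed, same bytes.

## Known limitations

* The classification thresholds are fixed bands, not a fitted classifier;
  movements near a boundary return `unclassified` by design.
* The curvature-origin fit assumes a single interior divergence point and
  at least three vertices per branch.
* The rhythmicity index depends on its bin width near degenerate
  histograms; the bin width used is always reported with the result.
* Event triggering at high smoothing merges within-burst potentials; for
  per-spike events, trigger on a lightly smoothed trace (one 0.3 ms pass),
  as the analysis scripts do.
* Pressure drag assumes rigid sections moving broadside; near-axial
  motion is flagged, not modelled.
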