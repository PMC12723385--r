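Package: struggleR
Title: Kinematics, Motor Rhythms and Escape Mechanics of Struggling Tadpoles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for studying how Xenopus tadpoles struggle
    free from a grip. Computes midline curvature-angle kinematics from
    pose-tracked body points (sum-of-angles traces, half-cycle structure,
    movement classification, propagation speed, curvature-origin detection),
    burst and rhythm statistics for ventral-root-like extracellular traces
    (rectify-and-smooth preprocessing, event triggering, burst grouping,
    rhythmicity index, cross-correlation propagation, spike-phase
    calibration), generates surrogate motoneuron spike commands statistically
    matched to recorded struggling and swimming activity, and evaluates the
    closed-form grip-friction, pressure-drag and lever models of escape.
    Includes ground-truth synthetic-data generators for traveling-wave
    midlines and multi-channel bursty traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
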