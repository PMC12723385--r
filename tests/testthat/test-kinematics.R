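test_that("curvature angles follow the arccos geometry with orientation sign", {
  # straight body: all nine angles exactly 0
  ang <- compute_curvature_angles(straight_body())
  expect_equal(ang$angles, matrix(0, 3, 9))
  expect_equal(ang$sum_trace, rep(0, 3))

  # right-angle turn at one vertex: a = (1,0), b = (0,1) -> |theta| = pi/2
  pts <- array(0, c(1, 11, 2))
  pts[1, , 1] <- c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  pts[1, , 2] <- c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  b <- tracked_body(pts, frame_rate = 100)
  a1 <- compute_curvature_angles(b)$angles[1, 1]
  expect_equal(abs(a1), pi / 2)

  # inscribed equilateral polyline over a full circle: each angle 2 pi / 10,
  # sum 9/10 of 2 pi; holds over rotations and radii, and the signed value
  # agrees with the arccos magnitude
  for (r in c(0.4, 1, 2.3)) {
    for (rot in c(0, 0.7, 2.1)) {
      ang <- compute_curvature_angles(circle_body(r, rot))
      expect_equal(abs(ang$angles[1, ]), rep(2 * pi / 10, 9),
                   tolerance = 1e-9)
      expect_equal(abs(ang$sum_trace[1]), 9 * 2 * pi / 10,
                   tolerance = 1e-9)
    }
  }
})

test_that("signed angle magnitude matches the arccos formula on random triples", {
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(rnorm(6), 3, 2)
    a <- p[2, ] - p[1, ]
    b <- p[3, ] - p[2, ]
    arccos <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    signed <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    expect_equal(abs(signed), arccos, tolerance = 1e-9)
  }
})

test_that("coincident points are flagged as missing, never silent zeros", {
  pts <- array(0, c(2, 11, 2))
  for (fr in 1:2) pts[fr, , 1] <- (0:10) * 0.5
  pts[2, 3, ] <- pts[2, 2, ]   # p3 coincides with p2 in frame 2
  ang <- compute_curvature_angles(tracked_body(pts, frame_rate = 100))
  expect_true(all(is.na(ang$angles[2, 1:2])))
  expect_equal(ang$n_flagged, 1L)
})

test_that("zero-phase low-pass passes the band and kills high frequencies", {
  fs <- 240
  t <- seq(0, 2, by = 1 / fs)
  lo <- sin(2 * pi * 5 * t)
  hi <- 0.5 * sin(2 * pi * 100 * t)
  as <- fake_angle_set(matrix(rep(lo + hi, 9), ncol = 9), fs)
  out <- lowpass_sum(as, cutoff = 50)
  mid <- seq(50, length(t) - 50)        # avoid filter edges
  resid_lo <- out$angles[mid, 1] - lo[mid]
  # 5 Hz passes within 1%; 100 Hz attenuated by >= 90%
  expect_lt(max(abs(resid_lo)), 0.1 * 0.5 + 0.01)
  expect_lt(stats::sd(resid_lo), 0.1 * stats::sd(hi))
  amp5 <- (max(out$angles[mid, 1]) - min(out$angles[mid, 1])) / 2
  expect_equal(amp5, 1, tolerance = 0.02)

  # constant trace unchanged; sum invariant preserved
  cst <- fake_angle_set(matrix(2, 200, 9), fs)
  outc <- lowpass_sum(cst, cutoff = 50)
  expect_equal(outc$angles, cst$angles, tolerance = 1e-9)
  expect_equal(outc$sum_trace, rowSums(outc$angles))

  expect_error(lowpass_sum(cst, cutoff = 120), "Nyquist")
})

test_that("half-cycle segmentation recovers sinusoid period and amplitude", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  for (A in c(0.8, 2.4)) {
    hc <- detect_half_cycles(A * sin(2 * pi * 7 * t), frame_rate = fs)
    expect_gt(nrow(hc), 20)
    expect_equal(mean(hc$duration), 1000 / 14, tolerance = 0.01)
    expect_equal(mean(hc$amplitude), A, tolerance = 0.01)
    expect_true(all(hc$duration > 0))
    expect_true(all(hc$amplitude >= 0))
    expect_true(all(abs(diff(hc$side)) == 2))  # alternating extrema
  }
  # constant trace: no half cycles
  expect_equal(nrow(detect_half_cycles(rep(1, 100), frame_rate = fs)), 0L)
})

test_that("synthetic struggling half-cycles are recovered within 5%", {
  b <- make_tracked_movement(wave_spec("struggling",
                                       amplitude = pi * 0.76,
                                       noise_sd = 0.01, seed = 3))
  ang <- lowpass_sum(compute_curvature_angles(b))
  hc <- detect_half_cycles(ang)
  expect_equal(mean(hc$duration), 125, tolerance = 0.05)
  expect_equal(mean(hc$amplitude), pi * 0.76, tolerance = 0.05)
})

test_that("movement classification reproduces the observed class structure", {
  mk <- function(amp, dur) data.frame(start = 0, end = dur / 1000,
                                      duration = dur, amplitude = amp,
                                      side = 1)
  expect_equal(classify_movement(mk(4.1, 183), NULL)$label,
               "initial_coiling")
  expect_equal(classify_movement(mk(4.1, 183), NULL,
                                 after_release = TRUE)$label,
               "transitional_coiling")
  expect_equal(classify_movement(mk(2.4, 71), fake_propagation(42.5))$label,
               "struggling")
  expect_equal(classify_movement(mk(1.0, 25), fake_propagation(-156))$label,
               "swimming")
  # wrong propagation direction for the amplitude band -> unclassified,
  # with distances to each class reported
  u <- classify_movement(mk(2.4, 71), fake_propagation(-156))
  expect_equal(u$label, "unclassified")
  expect_named(u$distances, c("coiling", "struggling", "swimming"))
  expect_error(classify_movement(mk(1, 10)[0, ], NULL), "half cycle")
})

test_that("classification orders amplitudes coiling > struggling > swimming", {
  amps <- vapply(c("initial_coiling", "struggling", "swimming"),
                 function(m) {
    b <- make_tracked_movement(wave_spec(m, noise_sd = 0.005, seed = 5))
    mean(detect_half_cycles(lowpass_sum(
      compute_curvature_angles(b)))$amplitude)
  }, numeric(1))
  expect_true(amps[1] > amps[2] && amps[2] > amps[3])
})

test_that("propagation speed is recovered from traveling waves", {
  # struggling-like wave at +42.5 mm/s
  b <- make_tracked_movement(wave_spec("struggling", noise_sd = 0.005,
                                       seed = 2))
  p <- propagation_speed(lowpass_sum(compute_curvature_angles(b)))
  expect_false(p$synchronous)
  expect_equal(p$speed, 42.5, tolerance = 0.05)
  expect_lt(p$regression_p, 0.001)

  # head-to-tail wave at 156 mm/s: negative sign
  b2 <- make_tracked_movement(wave_spec("swimming", propagation_speed = -156,
                                        noise_sd = 0.005, seed = 2))
  p2 <- propagation_speed(lowpass_sum(compute_curvature_angles(b2)))
  expect_equal(p2$speed, -156, tolerance = 0.05)

  # identical traces on all vertices: synchronous flag
  fs <- 240
  t <- seq(0, 2, by = 1 / fs)
  sync <- fake_angle_set(matrix(rep(sin(2 * pi * 4 * t), 9), ncol = 9), fs)
  ps <- propagation_speed(sync)
  expect_true(ps$synchronous)
  expect_true(is.na(ps$speed))
})

test_that("propagation speed is equivariant under time reversal and relabeling", {
  as <- fake_angle_set(wave_angles(4, 60), 240)
  sp <- propagation_speed(as)$speed
  rev_t <- as
  rev_t$angles <- as$angles[nrow(as$angles):1, ]
  rev_t$sum_trace <- rowSums(rev_t$angles)
  expect_equal(propagation_speed(rev_t)$speed, -sp, tolerance = 0.02)
  rev_v <- as
  rev_v$angles <- as$angles[, 9:1]
  expect_equal(propagation_speed(rev_v)$speed, -sp, tolerance = 0.02)
})

test_that("speeds 20-250 mm/s of both signs are recovered within 5% at SNR >= 10", {
  speeds <- c(20, -20, 60, -60, 150, -150, 250, -250)
  err <- vapply(speeds, function(v) {
    f <- if (abs(v) < 40) 2 else 4
    b <- make_tracked_movement(wave_spec("struggling", frequency = f,
                                         propagation_speed = v,
                                         noise_sd = 0.005, seed = 7))
    sp <- propagation_speed(lowpass_sum(compute_curvature_angles(b)))$speed
    abs(sp - v) / abs(v)
  }, numeric(1))
  expect_gte(mean(err < 0.05), 0.95)
})

test_that("curvature origin of a bidirectional wave is located with both speeds", {
  b <- make_tracked_movement(wave_spec("struggling", origin = 0.7,
                                       propagation_speed = 42.5,
                                       caudal_speed = -23.9,
                                       noise_sd = 0.005, seed = 4))
  o <- find_curvature_origin(lowpass_sum(compute_curvature_angles(b)))
  expect_equal(o$flag, "ok")
  expect_equal(o$origin_fraction, 0.70, tolerance = 0.072)  # +- 0.05 abs
  expect_lt(abs(o$origin_fraction - 0.70), 0.05)
  expect_true(o$caudal_significant)
  expect_equal(o$caudal_speed, -23.9, tolerance = 0.10)
  expect_gt(o$rostral_speed, 0)

  # unidirectional wave: no interior divergence point
  bu <- make_tracked_movement(wave_spec("struggling", noise_sd = 0.005,
                                        seed = 4))
  ou <- find_curvature_origin(lowpass_sum(compute_curvature_angles(bu)))
  expect_true(ou$flag %in% c("unidirectional", "undefined"))
  expect_true(is.na(ou$origin_fraction))
})

test_that("yaw is the peak-to-peak head-segment excursion per cycle", {
  # rigid rotation +-15 degrees -> 30 degrees of yaw
  fs <- 240
  t <- seq(0, 1, by = 1 / fs)
  pts <- array(0, c(length(t), 11, 2))
  for (fr in seq_along(t)) {
    th <- 15 * pi / 180 * sin(2 * pi * 4 * t[fr])
    pts[fr, , 1] <- (0:10) * 0.5 * cos(th)
    pts[fr, , 2] <- (0:10) * 0.5 * sin(th)
  }
  b <- tracked_body(pts, frame_rate = fs)
  cyc <- data.frame(start = c(0.25, 0.5), end = c(0.5, 0.75))
  expect_equal(compute_yaw(b, cyc), c(30, 30), tolerance = 0.01)

  # pure translation: zero yaw
  ptr <- array(0, c(length(t), 11, 2))
  for (fr in seq_along(t)) {
    ptr[fr, , 1] <- (0:10) * 0.5
    ptr[fr, , 2] <- t[fr] * 3
  }
  expect_equal(compute_yaw(tracked_body(ptr, frame_rate = fs), cyc), c(0, 0))

  # imposed heading oscillation +-52 degrees -> ~104 degrees
  bs <- make_tracked_movement(wave_spec("swimming", yaw_deg = 52,
                                        noise_sd = 0.005, seed = 9))
  y <- compute_yaw(bs, data.frame(start = 0.2, end = 0.25))
  expect_equal(y, 104, tolerance = 0.05)
})
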