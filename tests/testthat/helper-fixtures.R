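# Shared fixture builders for the test suite. All synthetic inputs are
# generated in code under fixed seeds.

# body of 11 points on a circle of radius r, spanning one full turn in 10
# equal arcs, rotated by `rot` radians
circle_body <- function(r = 1, rot = 0, n_frames = 2) {
  th <- rot + seq(0, 2 * pi, length.out = 11)
  pts <- array(NA_real_, c(n_frames, 11, 2))
  for (fr in seq_len(n_frames)) {
    pts[fr, , 1] <- r * cos(th)
    pts[fr, , 2] <- r * sin(th)
  }
  tracked_body(pts, frame_rate = 100, body_length = 5)
}

# straight body along +x
straight_body <- function(n_frames = 3) {
  pts <- array(0, c(n_frames, 11, 2))
  for (fr in seq_len(n_frames)) pts[fr, , 1] <- (0:10) * 0.5
  tracked_body(pts, frame_rate = 100, body_length = 5)
}

# minimal angle_set around given angle traces (frames x 9 matrix)
fake_angle_set <- function(angles, frame_rate, body_length = 5) {
  structure(list(angles = angles, sum_trace = rowSums(angles),
                 times = (seq_len(nrow(angles)) - 1) / frame_rate,
                 frame_rate = frame_rate,
                 vertex_positions = (1:9) / 10 * body_length,
                 body_length = body_length, filtered = TRUE, cutoff = NULL,
                 n_flagged = 0L),
            class = "angle_set")
}

# traveling-wave angle matrix: alpha_i(t) = a sin(2 pi f (t - pos_i / v))
wave_angles <- function(f, v, frame_rate = 240, duration = 3, a = 0.25,
                        body_length = 5) {
  times <- seq(0, duration, by = 1 / frame_rate)
  pos <- (1:9) / 10 * body_length
  s_ref <- if (v > 0) body_length else 0
  tau <- (s_ref - pos) / v
  outer(times, tau, function(t, d) a * sin(2 * pi * f * (t - d)))
}

fake_propagation <- function(speed) {
  structure(list(speed = speed, regression_p = 1e-6, n_lags = 9,
                 synchronous = is.na(speed),
                 lags = rep(NA_real_, 9), positions = (1:9) / 10 * 5),
            class = "propagation_estimate")
}
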