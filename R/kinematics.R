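# Midline kinematics: curvature angles, sum-of-angles, half-cycle
# segmentation, movement classification, propagation speed and
# curvature-origin detection.

#' Compute the nine signed body curvature angles
#'
#' At each interior tracked point the turning angle between the two segments
#' meeting there is computed: with \eqn{\vec a} running from the previous
#' point to the vertex and \eqn{\vec b} from the vertex to the next point,
#' the magnitude is \eqn{\theta = \cos^{-1}(\vec a\cdot\vec b /
#' |\vec a||\vec b|)} and the sign is taken from the orientation of the turn
#' in the tracking plane (cross-product z component; left bends positive).
#' A straight body gives nine zeros; the elementwise sum of the nine angles
#' (the sum-of-angles trace) summarises overall body shape: near \eqn{\pm2\pi}
#' the body is coiled in a C/O shape, near \eqn{\pm\pi} it is in a struggling
#' S shape, within \eqn{\pm0.5\pi} a swimming S shape.
#'
#' @param body a [tracked_body()].
#' @return An object of class `angle_set`: list with `angles` (frames x 9
#'   matrix, radians), `sum_trace`, `times`, `frame_rate`,
#'   `vertex_positions` (mm from head), `filtered` flag and `n_flagged`
#'   (frames with coincident/missing points, left NA).
#' @export
compute_curvature_angles <- function(body) {
  pts <- body$points
  n <- dim(pts)[1]
  ang <- matrix(NA_real_, n, 9)
  for (v in 2:10) {
    a_x <- pts[, v, 1] - pts[, v - 1, 1]
    a_y <- pts[, v, 2] - pts[, v - 1, 2]
    b_x <- pts[, v + 1, 1] - pts[, v, 1]
    b_y <- pts[, v + 1, 2] - pts[, v, 2]
    na <- sqrt(a_x^2 + a_y^2)
    nb <- sqrt(b_x^2 + b_y^2)
    dot <- a_x * b_x + a_y * b_y
    crs <- a_x * b_y - a_y * b_x
    bad <- is.na(na) | is.na(nb) | na == 0 | nb == 0
    th <- atan2(crs, dot)          # |atan2(cross, dot)| == acos(dot/|a||b|)
    th[bad] <- NA_real_
    ang[, v - 1] <- th
  }
  structure(
    list(angles = ang, sum_trace = rowSums(ang),
         times = body$times, frame_rate = body$frame_rate,
         vertex_positions = vertex_positions(body),
         body_length = body$body_length,
         filtered = FALSE, cutoff = NULL,
         n_flagged = sum(apply(is.na(ang), 1, any))),
    class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("<angle_set> %d frames @ %g fps%s, %d flagged\n",
              nrow(x$angles), x$frame_rate,
              if (x$filtered) sprintf(", low-passed at %g Hz", x$cutoff)
              else "", x$n_flagged))
  invisible(x)
}

#' Zero-phase low-pass filter of the angle traces
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass to
#' each of the nine angle traces; the sum trace is recomputed as the
#' elementwise sum of the filtered angles (filtering is linear, so this
#' equals filtering the sum). The unfiltered set is retained in `$raw`.
#' NA samples are bridged by linear interpolation for filtering and restored
#' afterwards.
#'
#' @param angle_set an `angle_set`.
#' @param cutoff cutoff frequency in Hz (default 50).
#' @return a filtered `angle_set`.
#' @export
lowpass_sum <- function(angle_set, cutoff = 50) {
  fs <- angle_set$frame_rate
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  filt1 <- function(v) {
    nas <- is.na(v)
    if (all(nas)) return(v)
    if (any(nas)) {
      ok <- which(!nas)
      v <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
    }
    # mirror-pad to suppress forward-backward filter edge transients
    np <- min(length(v) - 1L, max(60L, ceiling(12 * fs / cutoff)))
    n <- length(v)
    vp <- c(2 * v[1] - v[(np + 1):2], v, 2 * v[n] - v[(n - 1):(n - np)])
    out <- signal::filtfilt(bf, vp)[(np + 1):(np + n)]
    out[nas] <- NA_real_
    out
  }
  out <- angle_set
  out$angles <- apply(angle_set$angles, 2, filt1)
  out$sum_trace <- rowSums(out$angles)
  out$filtered <- TRUE
  out$cutoff <- cutoff
  out$raw <- angle_set
  out
}

#' Segment a sum-of-angles trace into half cycles
#'
#' A half cycle is one bend to one side: the interval between two successive
#' zero crossings of the mean-subtracted sum trace that bracket a single
#' extremum. Amplitude is half the peak/trough difference between the
#' extremum and the adjacent opposite extremum. Sub-threshold wiggles
#' (extrema below `min_amplitude` x the largest excursion) are discarded.
#'
#' @param x an `angle_set` (its `sum_trace` is used) or a numeric trace.
#' @param frame_rate sampling rate in Hz (taken from the `angle_set` when
#'   given).
#' @param min_amplitude relative threshold for accepting an extremum
#'   (fraction of the maximum excursion, default 0.1).
#' @return data.frame with columns `start`, `end` (s), `duration` (ms),
#'   `amplitude` (rad), `side` (+1 peak / -1 trough); zero rows when the
#'   trace holds less than one half cycle.
#' @export
detect_half_cycles <- function(x, frame_rate = NULL, min_amplitude = 0.1) {
  if (inherits(x, "angle_set")) {
    frame_rate <- x$frame_rate
    times <- x$times
    x <- x$sum_trace
  } else {
    stopifnot(!is.null(frame_rate))
    times <- (seq_along(x) - 1) / frame_rate
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      side = numeric(0))
  keep <- !is.na(x)
  x <- x[keep]
  times <- times[keep]
  if (length(x) < 3) return(empty)
  v <- x - mean(x)
  if (all(v == 0)) return(empty)
  s <- sign(v)
  s[s == 0] <- 1
  cross <- which(diff(s) != 0)
  if (length(cross) < 2) return(empty)
  # linearly interpolated crossing times
  ct <- times[cross] + (times[cross + 1] - times[cross]) *
    (0 - v[cross]) / (v[cross + 1] - v[cross])
  seg_start <- ct[-length(ct)]
  seg_end <- ct[-1]
  ext <- numeric(length(seg_start))
  for (i in seq_along(seg_start)) {
    idx <- (cross[i] + 1):cross[i + 1]
    ext[i] <- v[idx][which.max(abs(v[idx]))]
  }
  thr <- min_amplitude * max(abs(v))
  ok <- abs(ext) >= thr
  if (!any(ok)) return(empty)
  seg_start <- seg_start[ok]; seg_end <- seg_end[ok]; ext <- ext[ok]
  m <- length(ext)
  amp <- numeric(m)
  for (i in seq_len(m)) {
    adj <- if (i > 1) ext[i - 1] else if (m > 1) ext[i + 1] else -ext[i]
    amp[i] <- abs(ext[i] - adj) / 2
  }
  data.frame(start = seg_start, end = seg_end,
             duration = (seg_end - seg_start) * 1000,
             amplitude = amp, side = sign(ext))
}

#' Estimate the body-curvature propagation speed
#'
#' Cross-correlation is carried out between a reference angle (default
#' \eqn{\alpha_4}) and every other angle to extract the lag of the
#' correlation peak nearest zero; the speed is the slope of the regression
#' between vertex distance and lag. Sign convention: positive =
#' caudorostral (tail-to-head) propagation. Estimates whose regression is
#' not significant at `p_max` are reported as synchronous/unreliable with
#' no finite speed.
#'
#' @param angle_set a (preferably filtered) `angle_set`.
#' @param ref_index reference angle index 1-9 (default 4).
#' @param p_max regression significance cutoff for accepting a finite speed
#'   (default 0.05).
#' @return list of class `propagation_estimate`: `speed` (mm/s, positive
#'   caudorostral; NA when synchronous), `regression_p`, `n_lags`,
#'   `synchronous`, `lags` (s) and `positions` (mm).
#' @export
propagation_speed <- function(angle_set, ref_index = 4, p_max = 0.05) {
  stopifnot(inherits(angle_set, "angle_set"))
  dt <- 1 / angle_set$frame_rate
  ref <- angle_set$angles[, ref_index]
  if (anyNA(ref)) {
    ok <- !is.na(ref)
    ref[!ok] <- mean(ref, na.rm = TRUE)
  }
  per <- dominant_period(ref, dt)
  win <- if (is.na(per)) NULL else 0.6 * per
  lags <- rep(NA_real_, 9)
  for (i in 1:9) {
    y <- angle_set$angles[, i]
    if (anyNA(y)) {
      if (mean(is.na(y)) > 0.5) next
      okk <- which(!is.na(y))
      y <- stats::approx(okk, y[okk], xout = seq_along(y), rule = 2)$y
    }
    lags[i] <- cc_lag(ref, y, dt, window = win)$lag
  }
  usable <- which(is.finite(lags))
  if (length(usable) < 3)
    stop("fewer than 3 usable cross-correlation lags")
  pos <- angle_set$vertex_positions[usable]
  lg <- lags[usable]
  if (max(abs(lg)) < dt / 2) {   # all peaks at zero lag: synchronous
    return(structure(list(speed = NA_real_, regression_p = NA_real_,
                          n_lags = length(usable), synchronous = TRUE,
                          lags = lags,
                          positions = angle_set$vertex_positions),
                     class = "propagation_estimate"))
  }
  fit <- stats::lm(pos ~ lg)
  sm <- summary(fit)
  p <- sm$coefficients[2, 4]
  slope <- stats::coef(fit)[[2]]      # mm/s in the head-to-tail direction
  speed <- -slope                     # caudorostral positive
  synchronous <- !is.finite(p) || p >= p_max
  structure(list(speed = if (synchronous) NA_real_ else speed,
                 regression_p = p, n_lags = length(usable),
                 synchronous = synchronous, lags = lags,
                 positions = angle_set$vertex_positions),
            class = "propagation_estimate")
}

#' @export
print.propagation_estimate <- function(x, ...) {
  if (x$synchronous)
    cat(sprintf("<propagation> synchronous/unreliable (p = %.3g, n = %d)\n",
                x$regression_p, x$n_lags))
  else
    cat(sprintf("<propagation> %.1f mm/s (%s), p = %.3g, n = %d\n",
                x$speed,
                if (x$speed > 0) "caudorostral" else "rostrocaudal",
                x$regression_p, x$n_lags))
  invisible(x)
}

#' Classify a movement epoch
#'
#' Rule-based movement label from the mean sum-of-angles amplitude, half
#' cycle durations and propagation direction. Defaults place the class
#' boundaries between the mean amplitudes observed for the four movement
#' types: coiling near \eqn{\pm2\pi} (>= `coil_amp`), struggling near
#' \eqn{\pm\pi} with caudorostral propagation, swimming within
#' \eqn{\pm0.5\pi} with rostrocaudal propagation. Coiling after the release
#' marker is transitional coiling.
#'
#' @param half_cycles data.frame from [detect_half_cycles()].
#' @param propagation a `propagation_estimate` (or NULL for coiling epochs
#'   where no propagation is measurable).
#' @param after_release logical: does the epoch follow grip release?
#' @param coil_amp amplitude threshold for coiling, rad (default 3.2).
#' @param struggle_amp lower amplitude bound for struggling, rad
#'   (default 1.2).
#' @return list with `label` in `initial_coiling`, `struggling`,
#'   `transitional_coiling`, `swimming`, `unclassified`; `amplitude` (rad,
#'   mean), `half_cycle_ms` (mean) and, when unclassified, `distances` to
#'   each class band.
#' @export
classify_movement <- function(half_cycles, propagation = NULL,
                              after_release = FALSE,
                              coil_amp = 3.2, struggle_amp = 1.2) {
  if (nrow(half_cycles) < 1) stop("at least one half cycle is required")
  amp <- mean(half_cycles$amplitude)
  hc <- mean(half_cycles$duration)
  dir <- if (is.null(propagation) || propagation$synchronous) NA_real_
         else sign(propagation$speed)
  label <- "unclassified"
  if (amp >= coil_amp) {
    label <- if (after_release) "transitional_coiling" else "initial_coiling"
  } else if (amp >= struggle_amp) {
    if (is.na(dir) || dir > 0) label <- "struggling"
  } else {
    if (is.na(dir) || dir < 0) label <- "swimming"
  }
  out <- list(label = label, amplitude = amp, half_cycle_ms = hc)
  if (label == "unclassified") {
    out$distances <- c(
      coiling = max(0, coil_amp - amp),
      struggling = if (amp > coil_amp) amp - coil_amp
                   else max(0, struggle_amp - amp),
      swimming = max(0, amp - struggle_amp))
  }
  out
}

#' Locate the curvature origin of a bidirectional wave
#'
#' During struggling, body bends originate part-way down the body and
#' propagate toward both head and tail. Per-angle cross-correlation lags
#' (relative to a reference angle) are fitted, for every candidate split
#' vertex, by two separate position-vs-lag regressions rostral and caudal of
#' the split; the origin is the split minimising the pooled residual with
#' opposite-signed slopes, refined to the intersection of the two lines.
#'
#' @param angle_set a filtered `angle_set` covering a rhythmic epoch.
#' @param ref_index reference angle for the lags (default 4).
#' @param p_max significance cutoff for each one-sided regression.
#' @return list with `origin_fraction` (of body length; NA when
#'   undefined/unidirectional), `origin_mm`, `rostral_speed` (mm/s, positive
#'   caudorostral), `caudal_speed` (mm/s, negative rostrocaudal; NA with
#'   `caudal_significant = FALSE` when no caudal propagation is detected)
#'   and `flag` (`"ok"`, `"unidirectional"` or `"undefined"`).
#' @export
find_curvature_origin <- function(angle_set, ref_index = 4, p_max = 0.05) {
  stopifnot(inherits(angle_set, "angle_set"))
  dt <- 1 / angle_set$frame_rate
  ref <- angle_set$angles[, ref_index]
  per <- dominant_period(ref, dt)
  win <- if (is.na(per)) NULL else 0.6 * per
  lags <- vapply(1:9, function(i)
    cc_lag(ref, angle_set$angles[, i], dt, window = win)$lag, numeric(1))
  pos <- angle_set$vertex_positions
  ok <- is.finite(lags)
  if (sum(ok) < 5)
    return(list(origin_fraction = NA_real_, origin_mm = NA_real_,
                rostral_speed = NA_real_, caudal_speed = NA_real_,
                caudal_significant = FALSE, flag = "undefined"))
  best <- NULL
  for (k in 3:7) {
    ir <- which(ok & seq_along(lags) <= k)
    ic <- which(ok & seq_along(lags) >= k)
    if (length(ir) < 3 || length(ic) < 3) next
    fr <- stats::lm(lags[ir] ~ pos[ir])
    fc <- stats::lm(lags[ic] ~ pos[ic])
    sr <- stats::coef(fr)[[2]]
    sc <- stats::coef(fc)[[2]]
    if (!is.finite(sr) || !is.finite(sc) || sr >= 0 || sc <= 0) next
    rss <- sum(stats::resid(fr)^2) + sum(stats::resid(fc)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(k = k, rss = rss, fr = fr, fc = fc, sr = sr, sc = sc)
  }
  if (is.null(best))
    return(list(origin_fraction = NA_real_, origin_mm = NA_real_,
                rostral_speed = NA_real_, caudal_speed = NA_real_,
                caudal_significant = FALSE, flag = "unidirectional"))
  pr <- summary(best$fr)$coefficients[2, 4]
  pc <- summary(best$fc)$coefficients[2, 4]
  if (pr >= p_max && pc >= p_max)
    return(list(origin_fraction = NA_real_, origin_mm = NA_real_,
                rostral_speed = NA_real_, caudal_speed = NA_real_,
                caudal_significant = FALSE, flag = "undefined"))
  # intersection of the two lag-vs-position lines
  b1 <- stats::coef(best$fr); b2 <- stats::coef(best$fc)
  x0 <- (b2[[1]] - b1[[1]]) / (b1[[2]] - b2[[2]])
  x0 <- min(max(x0, 0), angle_set$body_length)
  list(origin_fraction = x0 / angle_set$body_length, origin_mm = x0,
       rostral_speed = if (pr < p_max) -1 / best$sr else NA_real_,
       caudal_speed = if (pc < p_max) -1 / best$sc else NA_real_,
       caudal_significant = pc < p_max,
       flag = "ok")
}

#' Yaw excursion of the head segment per cycle
#'
#' Yaw is the peak-to-peak angular excursion of the heading of the head
#' segment (p1 to p2) within each cycle window, in degrees.
#'
#' @param body a [tracked_body()].
#' @param cycles data.frame with `start` and `end` times in seconds (one row
#'   per cycle).
#' @return numeric vector of yaw angles in degrees (NA for windows with a
#'   degenerate head segment).
#' @export
compute_yaw <- function(body, cycles) {
  hx <- body$points[, 2, 1] - body$points[, 1, 1]
  hy <- body$points[, 2, 2] - body$points[, 1, 2]
  heading <- atan2(hy, hx)
  heading[sqrt(hx^2 + hy^2) == 0] <- NA_real_
  # unwrap
  d <- diff(heading)
  d[!is.na(d)] <- (d[!is.na(d)] + pi) %% (2 * pi) - pi
  heading <- cumsum(c(heading[1], ifelse(is.na(d), 0, d)))
  vapply(seq_len(nrow(cycles)), function(i) {
    idx <- body$times >= cycles$start[i] & body$times <= cycles$end[i]
    h <- heading[idx]
    if (sum(is.finite(h)) < 2) return(NA_real_)
    (max(h, na.rm = TRUE) - min(h, na.rm = TRUE)) * 180 / pi
  }, numeric(1))
}
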