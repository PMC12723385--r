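# Ground-truth generators emulating the study's raw inputs: traveling-wave
# midlines for the four movement types, and multi-channel bursty
# ventral-root-like traces. Every generator attaches its ground truth so
# the analysis modules can be validated closed-loop.

#' Specification of a synthetic tracked movement
#'
#' Presets centre the parameters on the kinematics observed for each
#' movement type: initial coiling (slow, near-synchronous, sum-of-angles
#' peak ~4.1 rad), struggling (4 Hz, ~2.4 rad, caudorostral at ~42.5 mm/s),
#' transitional coiling (~4 rad, fast rostrocaudal) and swimming (20 Hz,
#' ~1 rad, rostrocaudal at ~-156 mm/s).
#'
#' @param movement preset name.
#' @param frequency cycle frequency, Hz.
#' @param amplitude target peak of the sum-of-angles trace, rad.
#' @param propagation_speed signed mm/s (positive caudorostral); for
#'   bidirectional waves this is the rostral-branch speed.
#' @param origin curvature-origin fraction of body length in (0, 1), or NA
#'   for unidirectional waves.
#' @param caudal_speed caudal-branch speed, mm/s (negative = toward the
#'   tail); only used when `origin` is set.
#' @param duration duration in s.
#' @param frame_rate sampling rate in Hz.
#' @param body_length body length in mm.
#' @param yaw_deg amplitude of a sinusoidal head-heading oscillation in
#'   degrees (peak-to-peak yaw is twice this).
#' @param noise_sd coordinate noise SD, mm.
#' @param seed integer seed.
#' @return list of class `wave_spec`.
#' @export
wave_spec <- function(movement = c("struggling", "initial_coiling",
                                   "transitional_coiling", "swimming"),
                      frequency = NULL, amplitude = NULL,
                      propagation_speed = NULL, origin = NA,
                      caudal_speed = -23.9, duration = NULL,
                      frame_rate = 240, body_length = 5, yaw_deg = 0,
                      noise_sd = 0, seed = 1) {
  movement <- match.arg(movement)
  def <- switch(movement,
    initial_coiling      = list(f = 2.7, amp = 4.1, v = 400, dur = 2),
    struggling           = list(f = 4,   amp = 2.4, v = 42.5, dur = 3),
    transitional_coiling = list(f = 4,   amp = 4.0, v = -218, dur = 2),
    swimming             = list(f = 20,  amp = 1.0, v = -156, dur = 1.5))
  if (is.null(frequency)) frequency <- def$f
  if (is.null(amplitude)) amplitude <- def$amp
  if (is.null(propagation_speed)) propagation_speed <- def$v
  if (is.null(duration)) duration <- def$dur
  stopifnot(frequency > 0, frame_rate > 0, duration > 0)
  if (!is.na(origin) && (origin <= 0 || origin >= 1))
    stop("origin must be in (0, 1)")
  structure(list(movement = movement, frequency = frequency,
                 amplitude = amplitude,
                 propagation_speed = propagation_speed, origin = origin,
                 caudal_speed = caudal_speed, duration = duration,
                 frame_rate = frame_rate, body_length = body_length,
                 yaw_deg = yaw_deg, noise_sd = noise_sd, seed = seed),
            class = "wave_spec")
}

#' Generate a tracked midline movement from a wave specification
#'
#' A curvature wave is imposed on the nine interior vertices:
#' \eqn{\alpha_i(t) = a \sin(2\pi f (t - \tau(s_i)))} with the delay map
#' \eqn{\tau} encoding unidirectional propagation at the configured speed,
#' or bidirectional propagation diverging from the origin point. The
#' per-vertex amplitude `a` is scaled so the *sum* trace peaks at the
#' configured amplitude (the sum of phase-shifted sinusoids attenuates).
#' Coordinates are built by exact per-segment rotations from the head (no
#' small-angle approximation), so coiled shapes are representable; i.i.d.
#' Gaussian noise is added to coordinates.
#'
#' @param spec a [wave_spec()].
#' @return a [tracked_body()] with attribute `truth` (list: `frequency`,
#'   `sum_amplitude`, `vertex_amplitude`, `propagation_speed`, `origin`,
#'   `caudal_speed`, `half_cycle_ms`, `yaw_deg`).
#' @export
make_tracked_movement <- function(spec) {
  stopifnot(inherits(spec, "wave_spec"))
  L <- spec$body_length
  svert <- (1:9) / 10 * L
  f <- spec$frequency
  if (!is.na(spec$origin)) {
    s0 <- spec$origin * L
    vr <- spec$propagation_speed          # rostral branch, > 0 toward head
    vc <- abs(spec$caudal_speed)          # toward tail
    tau <- ifelse(svert <= s0, (s0 - svert) / vr, (svert - s0) / vc)
  } else {
    v <- spec$propagation_speed
    s_ref <- if (v > 0) L else 0
    tau <- (s_ref - svert) / v
  }
  # attenuation of the sum of phase-shifted unit sinusoids
  att <- Mod(sum(exp(-2i * pi * f * tau)))
  a <- if (att > 1e-6) spec$amplitude / att else 0
  if (a > 0.95 * pi) {
    warning("per-vertex amplitude capped below pi")
    a <- 0.95 * pi
  }
  n <- max(3L, round(spec$duration * spec$frame_rate))
  times <- (seq_len(n) - 1) / spec$frame_rate
  yaw_rad <- spec$yaw_deg * pi / 180
  h <- L / 10
  pts <- array(NA_real_, c(n, 11, 2))
  ang <- outer(times, tau, function(t, d) a * sin(2 * pi * f * (t - d)))
  head0 <- yaw_rad * sin(2 * pi * f * times)
  for (fr in seq_len(n)) {
    theta <- head0[fr] + cumsum(c(0, ang[fr, ]))   # headings of 10 segments
    x <- cumsum(c(0, h * cos(theta)))
    y <- cumsum(c(0, h * sin(theta)))
    pts[fr, , 1] <- x
    pts[fr, , 2] <- y
  }
  if (spec$noise_sd > 0)
    pts <- with_seed(spec$seed,
                     pts + stats::rnorm(length(pts), 0, spec$noise_sd))
  body <- tracked_body(pts, frame_rate = spec$frame_rate,
                       body_length = L, times = times)
  attr(body, "truth") <- list(
    frequency = f, sum_amplitude = spec$amplitude, vertex_amplitude = a,
    propagation_speed = spec$propagation_speed, origin = spec$origin,
    caudal_speed = if (is.na(spec$origin)) NA_real_ else spec$caudal_speed,
    half_cycle_ms = 1000 / (2 * f), yaw_deg = 2 * spec$yaw_deg)
  attr(body, "spec") <- spec
  body
}

#' Specification of synthetic ventral-root-like traces
#'
#' @param channels data.frame with columns `side` and `position_mm`.
#' @param burst_duration burst duration in ms.
#' @param cycle_period cycle period in ms (must exceed the burst duration).
#' @param propagation_speed mm/s (positive caudorostral).
#' @param event_rate_in_burst Hz (default 250).
#' @param jitter fraction of the cycle period jittering burst onsets
#'   (default 0).
#' @param dropout_per_mm per-event dropout probability per mm of electrode
#'   position (default 0; capped at 0.9).
#' @param sporadic_rate_per_mm rate (Hz per mm of electrode position) of
#'   sporadic background events outside the burst rhythm, emulating the
#'   less rhythmic firing of caudal recording sites (default 0).
#' @param noise_sd uV of Gaussian trace noise (default 2).
#' @param spike_amp uV amplitude of the biphasic event waveform (default
#'   100).
#' @param n_cycles number of cycles (default 12).
#' @param sampling_rate Hz (default 10000).
#' @param seed integer seed.
#' @return list of class `trace_spec`.
#' @export
trace_spec <- function(channels = data.frame(side = "left",
                                             position_mm = c(0.7, 1.2)),
                       burst_duration = 77, cycle_period = 250,
                       propagation_speed = 53.8,
                       event_rate_in_burst = 250, jitter = 0,
                       dropout_per_mm = 0, sporadic_rate_per_mm = 0,
                       noise_sd = 2, spike_amp = 100,
                       n_cycles = 12, sampling_rate = 10000, seed = 1) {
  stopifnot(burst_duration < cycle_period, jitter >= 0)
  structure(list(channels = channels, burst_duration = burst_duration,
                 cycle_period = cycle_period,
                 propagation_speed = propagation_speed,
                 event_rate_in_burst = event_rate_in_burst,
                 jitter = jitter, dropout_per_mm = dropout_per_mm,
                 sporadic_rate_per_mm = sporadic_rate_per_mm,
                 noise_sd = noise_sd, spike_amp = spike_amp,
                 n_cycles = n_cycles, sampling_rate = sampling_rate,
                 seed = seed),
            class = "trace_spec")
}

#' Generate multi-channel bursty traces from a trace specification
#'
#' Per channel, bursts of biphasic spike waveforms recur at the cycle
#' period, with burst onsets delayed according to the channel position and
#' propagation speed (caudal channels lead for positive speeds), optional
#' onset jitter, position-dependent event dropout, and additive Gaussian
#' noise. Ground-truth event times are attached per channel.
#'
#' @param spec a [trace_spec()].
#' @return list of [rhythm_trace()] objects with attribute `truth` (list
#'   with per-channel `event_times` in seconds and the spec).
#' @export
make_vr_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  fs <- spec$sampling_rate
  P <- spec$cycle_period / 1000
  nch <- nrow(spec$channels)
  pos <- spec$channels$position_mm
  pos_range <- range(pos)
  dur <- (spec$n_cycles + 2) * P
  nsamp <- round(dur * fs)
  tgrid <- (seq_len(nsamp) - 1) / fs
  # one biphasic cycle, 1.2 ms long
  wlen <- round(0.0012 * fs)
  wave <- spec$spike_amp * sin(2 * pi * seq_len(wlen) / wlen)
  isi <- 1 / spec$event_rate_in_burst
  n_ev <- max(1L, floor(spec$burst_duration / 1000 / isi) + 1L)
  traces <- vector("list", nch)
  truth <- vector("list", nch)
  with_seed(spec$seed, {
    for (ch in seq_len(nch)) {
      delay <- prop_delay_ms(pos[ch], spec$propagation_speed,
                             pos_range) / 1000
      ev <- c()
      for (cyc in seq_len(spec$n_cycles)) {
        onset <- P + (cyc - 1) * P + delay +
          if (spec$jitter > 0) stats::rnorm(1, 0, spec$jitter * P) else 0
        tt <- onset + (seq_len(n_ev) - 1) * isi
        p_drop <- min(0.9, spec$dropout_per_mm * pos[ch])
        if (p_drop > 0) {
          keep <- stats::runif(length(tt)) >= p_drop
          if (!any(keep)) keep[1] <- TRUE  # never drop a whole burst
          tt <- tt[keep]
        }
        ev <- c(ev, tt)
      }
      if (spec$sporadic_rate_per_mm > 0) {
        n_sp <- stats::rpois(1, spec$sporadic_rate_per_mm * pos[ch] * dur)
        if (n_sp > 0) ev <- c(ev, stats::runif(n_sp, 0, dur))
      }
      ev <- sort(ev)
      v <- numeric(nsamp)
      idx0 <- round(ev * fs)
      for (i0 in idx0) {
        sel <- (i0 + 1):(i0 + wlen)
        sel <- sel[sel >= 1 & sel <= nsamp]
        v[sel] <- v[sel] + wave[seq_along(sel)]
      }
      if (spec$noise_sd > 0)
        v <- v + stats::rnorm(nsamp, 0, spec$noise_sd)
      traces[[ch]] <- rhythm_trace(v, fs,
                                   side = spec$channels$side[ch],
                                   position = pos[ch])
      truth[[ch]] <- ev
    }
  })
  attr(traces, "truth") <- list(event_times = truth, spec = spec)
  traces
}
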