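# Burst and rhythm statistics for ventral-root-like extracellular traces.

#' Ventral-root-like rhythm trace
#'
#' @param samples numeric vector of voltage samples (uV).
#' @param sampling_rate Hz; recordings are expected to be digitized at
#'   >= 5000 Hz.
#' @param side `"left"` or `"right"`.
#' @param position electrode position in mm from the mid/hindbrain border
#'   (>= 0).
#' @param artifact_windows list of `c(start, end)` pairs in seconds to be
#'   truncated to 0 uV during preprocessing (declared, not inferred).
#' @return object of class `rhythm_trace`.
#' @export
rhythm_trace <- function(samples, sampling_rate, side = "left", position = 0,
                         artifact_windows = list()) {
  if (sampling_rate < 5000)
    stop("sampling_rate must be >= 5000 Hz")
  if (position < 0) stop("position must be >= 0 mm")
  side <- match.arg(side, c("left", "right"))
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, side = side,
                 position = position, artifact_windows = artifact_windows,
                 preprocessed = FALSE),
            class = "rhythm_trace")
}

#' @export
print.rhythm_trace <- function(x, ...) {
  cat(sprintf("<rhythm_trace> %s %.2f mm, %d samples @ %g kHz%s\n",
              x$side, x$position, length(x$samples),
              x$sampling_rate / 1000,
              if (x$preprocessed) " (rectified+smoothed)" else ""))
  invisible(x)
}

#' Rectify and smooth a trace
#'
#' Declared stimulus-artifact windows are truncated to 0 uV, the trace is
#' full-wave rectified, then smoothed by a centred moving average of
#' `smooth_window` ms applied `iterations` times (repeated boxcar
#' convolution, approaching a Gaussian kernel). Smoothing preserves total
#' signal mass for interior-supported signals.
#'
#' @param trace a [rhythm_trace()].
#' @param smooth_window moving-average window in ms (default 2.5).
#' @param iterations number of smoothing passes (default 4).
#' @return the preprocessed [rhythm_trace()].
#' @export
preprocess <- function(trace, smooth_window = 2.5, iterations = 4) {
  stopifnot(inherits(trace, "rhythm_trace"))
  fs <- trace$sampling_rate
  w <- round(smooth_window * fs / 1000)
  if (w < 3) stop("smoothing window must span at least 3 samples")
  if (w %% 2 == 0) w <- w + 1L
  v <- trace$samples
  for (aw in trace$artifact_windows) {
    idx <- which(seq_along(v) / fs >= aw[1] & seq_along(v) / fs <= aw[2])
    v[idx] <- 0
  }
  v <- abs(v)
  half <- (w - 1L) / 2L
  pad <- half * iterations
  v <- c(numeric(pad), v, numeric(pad))
  kern <- rep(1 / w, w)
  for (i in seq_len(iterations))
    v <- stats::filter(v, kern, sides = 2)
  v <- as.numeric(v)[(pad + 1):(pad + length(trace$samples))]
  v[is.na(v)] <- 0
  trace$samples <- v
  trace$preprocessed <- TRUE
  trace
}

#' Trigger events by threshold crossing
#'
#' The event threshold is k times the standard deviation of a baseline
#' window free of fictive swimming or struggling bursts, measured above the
#' baseline mean (a rectified trace has a nonzero noise floor). Events are
#' upward threshold crossings of the rectified trace, with a 1 ms
#' refractory period to avoid double-triggering on one potential.
#'
#' @param trace a preprocessed [rhythm_trace()].
#' @param baseline_window `c(start, end)` in seconds, inside the trace.
#' @param k threshold multiple of the baseline SD (default 5).
#' @param refractory_ms refractory period in ms (default 1).
#' @return object of class `event_train`: list with `event_times` (s,
#'   strictly increasing), `threshold` (uV) and `baseline_sd` (uV).
#' @export
trigger_events <- function(trace, baseline_window, k = 5,
                           refractory_ms = 1) {
  stopifnot(inherits(trace, "rhythm_trace"))
  fs <- trace$sampling_rate
  t <- (seq_along(trace$samples) - 1) / fs
  base <- trace$samples[t >= baseline_window[1] & t <= baseline_window[2]]
  if (length(base) < 2) stop("baseline window is empty")
  bsd <- stats::sd(base)
  thr <- k * bsd
  v <- trace$samples - mean(base)
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  if (length(up)) {
    # enforce refractory sequentially
    sel <- logical(length(up))
    last <- -Inf
    for (i in seq_along(up)) {
      if (t[up[i]] - last >= refractory_ms / 1000) {
        sel[i] <- TRUE
        last <- t[up[i]]
      }
    }
    up <- up[sel]
  }
  structure(list(event_times = t[up], threshold = thr, baseline_sd = bsd),
            class = "event_train")
}

#' Group triggered events into bursts and derive rhythm statistics
#'
#' Events closer than `max_gap` ms are merged into one burst per cycle.
#' Burst duration is last minus first event; the cycle period is the
#' interval between successive burst starts; duty cycle is mean burst
#' duration over mean cycle period.
#'
#' @param events an `event_train` or numeric vector of event times in
#'   seconds.
#' @param max_gap merge gap in ms (default 15, just above the 13 ms
#'   intra-burst inter-spike-interval bound).
#' @return list with `bursts` (data.frame: `start`, `end` s, `duration` ms,
#'   `n_events`) and `stats` (list: `cycle_period` ms, `frequency` Hz,
#'   `duty_cycle`, `n_bursts`; period is NA with `single_burst = TRUE` when
#'   everything merged into one burst).
#' @export
group_bursts <- function(events, max_gap = 15) {
  et <- if (inherits(events, "event_train")) events$event_times else events
  if (length(et) < 1)
    return(list(bursts = data.frame(start = numeric(0), end = numeric(0),
                                    duration = numeric(0),
                                    n_events = integer(0)),
                stats = list(cycle_period = NA_real_, frequency = NA_real_,
                             duty_cycle = NA_real_, n_bursts = 0L,
                             single_burst = FALSE)))
  et <- sort(et)
  brk <- which(diff(et) > max_gap / 1000)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(et))
  bursts <- data.frame(start = et[starts], end = et[ends],
                       duration = (et[ends] - et[starts]) * 1000,
                       n_events = ends - starts + 1L)
  nb <- nrow(bursts)
  if (nb < 2) {
    stats <- list(cycle_period = NA_real_, frequency = NA_real_,
                  duty_cycle = NA_real_, n_bursts = nb,
                  single_burst = nb == 1L)
  } else {
    period <- mean(diff(bursts$start)) * 1000
    stats <- list(cycle_period = period, frequency = 1000 / period,
                  duty_cycle = mean(bursts$duration) / period,
                  n_bursts = nb, single_burst = FALSE)
  }
  list(bursts = bursts, stats = stats)
}

#' Rhythmicity index from the inter-event-interval histogram
#'
#' Consecutive inter-event intervals are histogrammed at `bin_width` ms and
#' smoothed with a 3-bin moving average. Scanning from short intervals, the
#' first trough (local minimum after the initial peak, or the empty region
#' preceding the first peak for trains without short-interval structure) and
#' the following peak give \eqn{R = (peak - trough)/(peak + trough)}.
#' R = 1 means perfectly rhythmic; unimodal histograms with no interior
#' trough give R = 0 with `flag = "unimodal"`.
#'
#' @param event_times event times in seconds (or an `event_train`).
#' @param bin_width histogram bin width in ms (default 5).
#' @return list with `R` in `[0, 1]`, `flag` (`"ok"` or `"unimodal"`),
#'   `bin_width`, `peak`, `trough` (smoothed counts).
#' @export
rhythmicity_index <- function(event_times, bin_width = 5) {
  et <- if (inherits(event_times, "event_train")) event_times$event_times
        else event_times
  isi <- diff(sort(et)) * 1000
  if (length(isi) < 10)
    stop("at least 10 inter-event intervals are required")
  nb <- ceiling(max(isi) / bin_width) + 1L
  counts <- tabulate(pmin(nb, floor(isi / bin_width) + 1L), nbins = nb)
  sm <- as.numeric(stats::filter(c(0, counts, 0), rep(1 / 3, 3),
                                 sides = 2))[2:(nb + 1)]
  n <- length(sm)
  if (n < 3) return(list(R = 0, flag = "unimodal", bin_width = bin_width,
                         peak = NA_real_, trough = NA_real_))
  locmax <- which(c(sm[1] > sm[2],
                    sm[2:(n - 1)] >= sm[1:(n - 2)] &
                    sm[2:(n - 1)] >= sm[3:n] &
                    sm[2:(n - 1)] > 0,
                    sm[n] > sm[n - 1] & sm[n] > 0))
  if (!length(locmax))
    return(list(R = 0, flag = "unimodal", bin_width = bin_width,
                peak = NA_real_, trough = NA_real_))
  p1 <- locmax[1]
  later <- locmax[locmax > p1]
  # negligible stray bumps (isolated intervals) are not peaks
  if (length(later))
    later <- later[sm[later] >= 0.25 * max(sm[later])]
  if (length(later)) {
    # first trough after the initial peak, then the first following peak
    p2 <- later[1]
    trough_i <- p1 + which.min(sm[(p1 + 1):p2])
    trough <- sm[trough_i]
    peak <- sm[p2]
    if (trough >= peak)
      return(list(R = 0, flag = "unimodal", bin_width = bin_width,
                  peak = peak, trough = trough))
    R <- (peak - trough) / (peak + trough)
    return(list(R = max(0, min(1, R)), flag = "ok", bin_width = bin_width,
                peak = peak, trough = trough))
  }
  # single mode: if preceded by an empty region (rhythmic train with all
  # intervals near the cycle period) the leading trough is 0 and R = 1
  if (p1 > 1 && min(sm[1:(p1 - 1)]) < sm[p1]) {
    trough <- min(sm[1:(p1 - 1)])
    peak <- sm[p1]
    R <- (peak - trough) / (peak + trough)
    return(list(R = max(0, min(1, R)), flag = "ok", bin_width = bin_width,
                peak = peak, trough = trough))
  }
  list(R = 0, flag = "unimodal", bin_width = bin_width,
       peak = sm[p1], trough = NA_real_)
}

#' Rhythm propagation between two channels
#'
#' The propagation delay between two same-side ventral-root channels is the
#' cross-correlation local maximum nearest zero lag; speed is the electrode
#' distance over the delay. Sign convention: positive = caudorostral (the
#' caudal channel leads).
#'
#' @param traceA,traceB preprocessed [rhythm_trace()] objects at different
#'   positions.
#' @param window optional lag search half-window in seconds (default 0.6 x
#'   dominant period).
#' @param sync_tol delays smaller than this many samples are reported as
#'   synchronous (default 0.5).
#' @return list with `delay_ms` (rostral time minus caudal time; positive
#'   when the caudal channel leads), `speed` (mm/s, positive caudorostral;
#'   NA when synchronous or undefined), `synchronous`, `flag`.
#' @export
xcorr_propagation <- function(traceA, traceB, window = NULL,
                              sync_tol = 0.5) {
  stopifnot(inherits(traceA, "rhythm_trace"),
            inherits(traceB, "rhythm_trace"))
  if (traceA$position == traceB$position)
    stop("channel positions must differ")
  fs <- traceA$sampling_rate
  if (traceB$sampling_rate != fs) stop("sampling rates must match")
  n <- min(length(traceA$samples), length(traceB$samples))
  # order so that `ros` is the rostral channel
  if (traceA$position < traceB$position) {
    ros <- traceA; cau <- traceB
  } else {
    ros <- traceB; cau <- traceA
  }
  res <- cc_lag(cau$samples[1:n], ros$samples[1:n], 1 / fs, window = window)
  if (is.na(res$lag))
    return(list(delay_ms = NA_real_, speed = NA_real_, synchronous = FALSE,
                flag = "undefined"))
  delay <- res$lag   # >0: rostral lags caudal -> caudorostral
  if (abs(delay) < sync_tol / fs)
    return(list(delay_ms = delay * 1000, speed = NA_real_,
                synchronous = TRUE, flag = "synchronous"))
  dist_mm <- abs(cau$position - ros$position)
  list(delay_ms = delay * 1000, speed = dist_mm / delay,
       synchronous = FALSE, flag = "ok")
}

#' Calibrated spike phases within struggling cycles
#'
#' Raw phase is (spike time - cycle onset)/cycle period. The rostrocaudal
#' phase delay is calibrated with the standard delay
#' 0.185 - 0.00225 x cycle period (period in seconds) over a reference
#' distance of 1.65 mm, scaled by the actual separation `distance_L`;
#' 0.5 is added for contralateral recordings. Phases are wrapped to
#' (-0.5, 0.5] with the boundary mapped to +0.5.
#'
#' @param spike_times spike times in seconds.
#' @param cycle_onsets cycle onset times in seconds (sorted); each spike is
#'   assigned to the latest onset not after it.
#' @param distance_L rostrocaudal separation between the neuron and the
#'   reference ventral-root recording, mm.
#' @param contralateral logical: was the reference recorded on the opposite
#'   side?
#' @param cycle_period cycle period in seconds; default: mean onset
#'   interval.
#' @return numeric vector of calibrated phases in (-0.5, 0.5].
#' @export
phase_of_spikes <- function(spike_times, cycle_onsets, distance_L = 0,
                            contralateral = FALSE, cycle_period = NULL) {
  cycle_onsets <- sort(cycle_onsets)
  if (is.null(cycle_period)) {
    if (length(cycle_onsets) < 2)
      stop("cycle_period must be given when fewer than 2 onsets")
    cycle_period <- mean(diff(cycle_onsets))
  }
  if (cycle_period <= 0) stop("cycle period must be > 0")
  idx <- findInterval(spike_times, cycle_onsets)
  if (any(idx == 0)) stop("cycle onsets must bracket all spikes")
  raw <- (spike_times - cycle_onsets[idx]) / cycle_period
  cal <- raw - (0.185 - 0.00225 * cycle_period) * (distance_L / 1.65)
  if (contralateral) cal <- cal - 0.5
  # wrap to (-0.5, 0.5], boundary -> +0.5
  ph <- cal - round(cal)
  ph[ph == -0.5] <- 0.5
  ph
}
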