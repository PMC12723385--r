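# Cross-correlation lag machinery shared by the kinematics and rhythm
# modules: both estimate propagation by picking the cross-correlation local
# maximum nearest zero lag and regressing position on lag.

#' Cross-correlation lag nearest zero
#'
#' Computes the cross-correlation of two mean-subtracted traces and returns
#' the lag of the local maximum nearest zero lag, refined by parabolic
#' interpolation. Positive lag means `y` is delayed relative to `x`.
#' The search window defaults to 0.6 of the dominant cycle period of `x`
#' (rhythms can alias at one full period, so the peak "close to 0" is the
#' one sought).
#'
#' @param x,y numeric traces sampled at `dt` second intervals.
#' @param dt sample interval in seconds.
#' @param window half-width of the lag search window in seconds; `NULL`
#'   (default) uses 0.6 x the dominant period of `x`.
#' @return list with `lag` (seconds; NA if no interior local maximum),
#'   `peak` (correlation at the peak) and `window` (seconds, as used).
#' @export
cc_lag <- function(x, y, dt, window = NULL) {
  stopifnot(length(x) == length(y), dt > 0)
  if (is.null(window)) {
    per <- dominant_period(x, dt)
    window <- if (is.na(per)) (length(x) - 1) * dt / 4 else 0.6 * per
  }
  x0 <- x - mean(x)
  y0 <- y - mean(y)
  kmax <- min(length(x) - 2L, max(2L, ceiling(window / dt)))
  lags <- -kmax:kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(x0[1:(length(x0) - k)] * y0[(1 + k):length(y0)])
    else        sum(x0[(1 - k):length(x0)] * y0[1:(length(y0) + k)])
  }, numeric(1))
  denom <- sqrt(sum(x0^2) * sum(y0^2))
  if (denom == 0) return(list(lag = NA_real_, peak = NA_real_,
                              window = window))
  cc <- cc / denom
  n <- length(cc)
  is_max <- c(FALSE, cc[2:(n - 1)] >= cc[1:(n - 2)] &
                     cc[2:(n - 1)] >= cc[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(list(lag = NA_real_, peak = NA_real_,
                                 window = window))
  # Pick the peak nearest zero among genuine correlation lobes: the global
  # maximum, plus near-maximal local maxima separated from it by a real dip
  # (alias peaks of a rhythm are; noise ripples on the main lobe are not).
  g <- cand[which.max(cc[cand])]
  sep <- vapply(cand, function(m) {
    if (m == g) return(TRUE)
    min(cc[min(m, g):max(m, g)]) < 0.5 * cc[g]
  }, logical(1))
  cand <- cand[sep & cc[cand] >= 0.8 * cc[g]]
  best <- cand[order(abs(lags[cand]), -cc[cand])][1]
  # parabolic refinement of the peak position
  delta <- 0
  den <- cc[best - 1] - 2 * cc[best] + cc[best + 1]
  if (is.finite(den) && den < 0)
    delta <- 0.5 * (cc[best - 1] - cc[best + 1]) / den
  list(lag = (lags[best] + delta) * dt, peak = cc[best], window = window)
}

#' Dominant cycle period of a rhythmic trace
#'
#' First positive-lag local maximum of the autocorrelation function.
#'
#' @param x numeric trace.
#' @param dt sample interval in seconds.
#' @return period in seconds, or NA when the trace has no interior
#'   autocorrelation peak (e.g. constant or aperiodic traces).
#' @export
dominant_period <- function(x, dt) {
  x0 <- x - mean(x)
  if (all(x0 == 0)) return(NA_real_)
  n <- length(x0)
  ac <- stats::acf(x0, lag.max = n - 2L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  m <- length(ac)
  if (m < 4) return(NA_real_)
  # skip the zero-lag peak: first local min, then the next local max
  i <- 2L
  while (i < m && ac[i] <= ac[i - 1]) i <- i + 1L
  while (i < m && ac[i + 1] >= ac[i]) i <- i + 1L
  if (i >= m || ac[i] <= 0) return(NA_real_)
  (i - 1) * dt
}

# Brute-force lag search used only as an independent oracle in tests:
# enumerates every integer shift and returns the shift maximising the
# overlap correlation.
bruteforce_best_shift <- function(x, y, kmax) {
  x0 <- x - mean(x)
  y0 <- y - mean(y)
  vals <- vapply(-kmax:kmax, function(k) {
    if (k >= 0) sum(x0[1:(length(x0) - k)] * y0[(1 + k):length(y0)])
    else        sum(x0[(1 - k):length(x0)] * y0[1:(length(y0) + k)])
  }, numeric(1))
  (-kmax:kmax)[which.max(vals)]
}
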