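# Surrogate motoneuron spike commands: roster construction, ECDF-based
# spike-count and inter-spike-interval generalisation, and the
# struggle/swim/reverse/initial-coil command variants used to drive a
# biomechanical tadpole model.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build the motoneuron roster from a per-100-um density table
#'
#' The packaged default table spans 0.5 to 4.8 mm from the mid/hindbrain
#' border and pins the anatomical totals: 248 motoneurons per side rostral
#' of 3.0 mm (backfill counts) plus a caudal extension at a density
#' decreasing from 4 to 2 per 100 um, for 311 per side in the full roster.
#' Positions are deterministic: uniformly spread within each 100 um bin.
#' The packaged per-bin values are a synthetic digitization pinned to those
#' totals, not measured counts.
#'
#' @param fixture data.frame with columns `bin_start_mm`, `bin_end_mm`,
#'   `count`, or a path to such a CSV; default: the packaged table.
#' @param max_position optional cap in mm (e.g. 3.0 reproduces the 248-cell
#'   backfill roster).
#' @return data.frame of class `motoneuron_roster` with columns `id`,
#'   `side` (`"L"`/`"R"`) and `position_mm`, sorted by side then position.
#' @export
build_roster <- function(fixture = NULL, max_position = NULL) {
  if (is.null(fixture))
    fixture <- system.file("extdata", "motoneuron_density.csv",
                           package = "struggleR", mustWork = TRUE)
  if (is.character(fixture))
    fixture <- utils::read.csv(fixture, comment.char = "#")
  stopifnot(all(c("bin_start_mm", "bin_end_mm", "count") %in%
                names(fixture)))
  if (nrow(fixture) &&
      (min(fixture$bin_start_mm) < 0.5 - 1e-9 ||
       max(fixture$bin_end_mm) > 4.8 + 1e-9))
    stop("fixture bins must lie within [0.5, 4.8] mm")
  if (!is.null(max_position))
    fixture <- fixture[fixture$bin_end_mm <= max_position + 1e-9, ]
  pos <- unlist(lapply(seq_len(nrow(fixture)), function(i) {
    n <- fixture$count[i]
    if (n < 1) return(numeric(0))
    w <- fixture$bin_end_mm[i] - fixture$bin_start_mm[i]
    fixture$bin_start_mm[i] + (seq_len(n) - 0.5) / n * w
  }))
  pos <- sort(pos)
  n <- length(pos)
  out <- data.frame(id = c(seq_len(n), seq_len(n)),
                    side = rep(c("L", "R"), each = n),
                    position_mm = c(pos, pos))
  class(out) <- c("motoneuron_roster", "data.frame")
  out
}

#' Inverse-transform sampling from an empirical distribution
#'
#' Draws from the linearly interpolated empirical CDF of `source_sample`
#' (inverse-transform sampling: uniform draws pushed through the
#' interpolated sample quantile function). Draws stay within the source
#' support and reproduce its distribution for large n.
#'
#' @param source_sample non-empty numeric sample defining the distribution.
#' @param n number of draws (>= 0).
#' @param seed optional integer; when given, draws are reproducible and the
#'   global RNG state is left untouched.
#' @return numeric vector of n draws.
#' @export
ecdf_sample <- function(source_sample, n, seed = NULL) {
  if (!length(source_sample)) stop("source_sample must be non-empty")
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(numeric(0))
  with_seed(seed,
    as.numeric(stats::quantile(source_sample, stats::runif(n), type = 7,
                               names = FALSE)))
}

#' Packaged inter-spike-interval stand-in samples
#'
#' The recorded ISI samples behind the published commands are not deposited;
#' the default source is a parametric stand-in: a log-normal with median
#' 5 ms, truncated to (0, 13] ms (intervals above 13 ms are excluded as
#' likely spanning different bursts). Returned as a deterministic
#' quantile-grid sample so the machinery is seed-independent; swap in real
#' recorded samples via the `isi_source` config field.
#'
#' @param region `"rostral"` or `"caudal"` (same stand-in family; kept
#'   separate so user-supplied samples can differ by region).
#' @param n sample size (default 512).
#' @param median_ms,sdlog log-normal parameters (defaults 5 ms, 0.5).
#' @param max_ms truncation bound in ms (default 13).
#' @return numeric vector of ISI values in ms, all in (0, max_ms].
#' @export
isi_standin <- function(region = c("rostral", "caudal"), n = 512,
                        median_ms = 5, sdlog = 0.5, max_ms = 13) {
  region <- match.arg(region)
  p_hi <- stats::plnorm(max_ms, log(median_ms), sdlog)
  p <- (seq_len(n) - 0.5) / n * p_hi
  stats::qlnorm(p, log(median_ms), sdlog)
}

#' Configuration for a surrogate command
#'
#' Defaults encode the published design targets per pattern: struggling at
#' 4 Hz with caudorostral propagation at +40 mm/s, duty cycle 0.4 (rostral)
#' rising to 0.6 (tail), spikes per burst falling from a mean of 6.1
#' (rostral) to 1.9 (caudal); swimming at 20 Hz, one spike per neuron per
#' cycle, rostrocaudal at -130 mm/s; reverse variants negate the
#' propagation; the initial coil fires a single 15-spike burst per neuron
#' with near-zero longitudinal delay.
#'
#' @param pattern one of `"struggle"`, `"reverse_struggle"`, `"swim"`,
#'   `"reverse_swim"`, `"initial_coil"`.
#' @param frequency cycle frequency, Hz.
#' @param propagation_speed signed mm/s; positive = caudorostral.
#' @param duty_rostral,duty_caudal duty-cycle profile endpoints at 0.5 and
#'   4.8 mm (linear in between).
#' @param spikes_mean,spikes_sd spike-count distribution endpoints (rostral,
#'   caudal); discretized normal truncated at >= 1.
#' @param isi_source list with `rostral` and `caudal` ISI samples in ms
#'   (defaults: [isi_standin()]); intervals above `isi_max_ms` are excluded
#'   from the source before sampling.
#' @param isi_max_ms intra-burst ISI bound, ms (default 13).
#' @param n_cycles number of cycles (default 8).
#' @param jitter_ms half-width of the uniform burst-centre jitter (default
#'   4 ms; 0 for the initial coil).
#' @param seed integer seed controlling every draw.
#' @return list of class `command_config`.
#' @export
command_config <- function(pattern = c("struggle", "reverse_struggle",
                                       "swim", "reverse_swim",
                                       "initial_coil"),
                           frequency = NULL, propagation_speed = NULL,
                           duty_rostral = 0.4, duty_caudal = 0.6,
                           spikes_mean = c(6.1, 1.9),
                           spikes_sd = c(4.1, 0.9),
                           isi_source = NULL, isi_max_ms = 13,
                           n_cycles = 8, jitter_ms = 4, seed = 1) {
  pattern <- match.arg(pattern)
  if (is.null(frequency))
    frequency <- switch(pattern, swim = 20, reverse_swim = 20,
                        initial_coil = 4, 4)
  if (is.null(propagation_speed))
    propagation_speed <- switch(pattern,
                                struggle = 40, reverse_struggle = -40,
                                swim = -130, reverse_swim = 130,
                                initial_coil = 0)
  if (frequency <= 0) stop("frequency must be > 0")
  if (pattern != "initial_coil" && propagation_speed == 0)
    stop("propagation_speed must be non-zero for rhythmic patterns")
  if (is.null(isi_source))
    isi_source <- list(rostral = isi_standin("rostral"),
                       caudal = isi_standin("caudal"))
  isi_source <- lapply(isi_source, function(s) s[s <= isi_max_ms & s > 0])
  if (pattern == "initial_coil") jitter_ms <- 0
  structure(list(pattern = pattern, frequency = frequency,
                 propagation_speed = propagation_speed,
                 duty_rostral = duty_rostral, duty_caudal = duty_caudal,
                 spikes_mean = spikes_mean, spikes_sd = spikes_sd,
                 isi_source = isi_source, isi_max_ms = isi_max_ms,
                 n_cycles = n_cycles, jitter_ms = jitter_ms, seed = seed),
            class = "command_config")
}

# Burst-merge gap separating cycles of a command: half the cycle period,
# capped at 50 ms (intra-burst ISIs are bounded by 13 ms).
default_merge_gap <- function(table) {
  cfg <- attr(table, "config")
  f <- if (!is.null(cfg) && !is.null(cfg$frequency)) cfg$frequency else 10
  min(50, 500 / f)
}

interp_pos <- function(p, lo, hi, p0 = 0.5, p1 = 4.8) {
  f <- pmin(1, pmax(0, (p - p0) / (p1 - p0)))
  lo + f * (hi - lo)
}

# Signed propagation delay of the burst centre at position p (ms); the
# leading end is the body end the wave starts from (tail for caudorostral
# speeds, head for rostrocaudal).
prop_delay_ms <- function(p, v, pos_range) {
  if (v == 0) return(rep(0, length(p)))
  p_ref <- if (v > 0) pos_range[2] else pos_range[1]
  (p_ref - p) / v * 1000
}

#' Generate a surrogate struggling command
#'
#' Left and right sides burst in anti-phase at the configured frequency.
#' The propagation delay (position over speed; caudal neurons lead for
#' caudorostral speeds) is applied to burst centres; each neuron's spike
#' count is drawn from the position-dependent discretized normal, its
#' inter-spike intervals from the (position-dependent) empirical ISI
#' source, and the burst is centred in the local duty-cycle window with a
#' small uniform jitter. Bursts longer than the duty window are truncated
#' with a warning.
#'
#' @param config a [command_config()] (pattern `"struggle"` or
#'   `"reverse_struggle"`).
#' @param roster a [build_roster()] roster.
#' @return a `spike_table`: data.frame with `neuron_id`, `side`,
#'   `position_mm`, `spike_time_ms`, with the config and seed attached as
#'   attributes.
#' @export
generate_struggle <- function(config = command_config("struggle"),
                              roster = build_roster()) {
  stopifnot(inherits(config, "command_config"))
  period <- 1000 / config$frequency
  pos_range <- range(roster$position_mm)
  lead_in <- period   # keeps all times non-negative under jitter/delays
  truncated <- 0L
  rows <- with_seed(config$seed, {
    out <- vector("list", nrow(roster) * config$n_cycles)
    k <- 0L
    for (side in c("L", "R")) {
      sub <- roster[roster$side == side, ]
      sub <- sub[order(sub$position_mm, sub$id), ]
      side_off <- if (side == "L") 0 else period / 2
      for (i in seq_len(nrow(sub))) {
        p <- sub$position_mm[i]
        d <- prop_delay_ms(p, config$propagation_speed, pos_range)
        w <- interp_pos(p, config$duty_rostral, config$duty_caudal) * period
        mu <- interp_pos(p, config$spikes_mean[1], config$spikes_mean[2])
        sdv <- interp_pos(p, config$spikes_sd[1], config$spikes_sd[2])
        src <- if (p <= 2.2) config$isi_source$rostral
               else config$isi_source$caudal
        for (cyc in seq_len(config$n_cycles)) {
          n_sp <- max(1L, round(stats::rnorm(1, mu, sdv)))
          isis <- if (n_sp > 1)
            as.numeric(stats::quantile(src, stats::runif(n_sp - 1),
                                       type = 7, names = FALSE))
          else numeric(0)
          rel <- c(0, cumsum(isis))
          if (max(rel) > w) {
            truncated <- truncated + 1L
            rel <- rel[rel <= w]
          }
          # place the burst uniformly within the local duty-cycle window,
          # centred on the propagation-delayed window centre so the
          # placement adds no position-dependent bias
          slack <- (w - max(rel)) / 2
          centre <- lead_in + (cyc - 1) * period + side_off + d +
            stats::runif(1, -slack, slack) +
            stats::runif(1, -config$jitter_ms, config$jitter_ms)
          k <- k + 1L
          out[[k]] <- data.frame(neuron_id = sub$id[i], side = side,
                                 position_mm = p,
                                 spike_time_ms = centre - max(rel) / 2 + rel)
        }
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  if (truncated > 0)
    warning(truncated, " burst(s) exceeded the duty-cycle window and were ",
            "truncated")
  rows <- rows[order(rows$side, rows$position_mm, rows$neuron_id,
                     rows$spike_time_ms), ]
  rownames(rows) <- NULL
  attr(rows, "config") <- config
  class(rows) <- c("spike_table", "data.frame")
  rows
}

#' Generate a surrogate swimming command
#'
#' 20 Hz rhythm, one spike per neuron per cycle, rostrocaudal propagation at
#' -130 mm/s by default (reverse swimming negates the delay map).
#'
#' @param config a [command_config()] (pattern `"swim"` or
#'   `"reverse_swim"`).
#' @param roster a [build_roster()] roster.
#' @return a `spike_table`.
#' @export
generate_swim <- function(config = command_config("swim"),
                          roster = build_roster()) {
  stopifnot(inherits(config, "command_config"))
  period <- 1000 / config$frequency
  pos_range <- range(roster$position_mm)
  lead_in <- period
  rows <- with_seed(config$seed, {
    out <- vector("list", 2L)
    for (s in 1:2) {
      side <- c("L", "R")[s]
      sub <- roster[roster$side == side, ]
      sub <- sub[order(sub$position_mm, sub$id), ]
      side_off <- if (side == "L") 0 else period / 2
      d <- prop_delay_ms(sub$position_mm, config$propagation_speed,
                         pos_range)
      g <- expand.grid(i = seq_len(nrow(sub)),
                       cyc = seq_len(config$n_cycles))
      jit <- stats::runif(nrow(g), -config$jitter_ms, config$jitter_ms)
      out[[s]] <- data.frame(
        neuron_id = sub$id[g$i], side = side,
        position_mm = sub$position_mm[g$i],
        spike_time_ms = lead_in + (g$cyc - 1) * period + side_off +
          d[g$i] + jit)
    }
    do.call(rbind, out)
  })
  rows <- rows[order(rows$side, rows$position_mm, rows$neuron_id,
                     rows$spike_time_ms), ]
  rownames(rows) <- NULL
  attr(rows, "config") <- config
  class(rows) <- c("spike_table", "data.frame")
  rows
}

#' Reverse the propagation of a command
#'
#' Regenerates the command with the propagation-speed sign flipped and the
#' same seed, so each neuron keeps an identical spike multiset while the
#' position-delay map is negated. Applying it twice returns the original
#' command.
#'
#' @param x a `spike_table` or a [command_config()].
#' @return a `spike_table`.
#' @export
generate_reverse <- function(x) {
  config <- if (inherits(x, "spike_table")) attr(x, "config") else x
  stopifnot(inherits(config, "command_config"))
  flipped <- switch(config$pattern,
                    struggle = "reverse_struggle",
                    reverse_struggle = "struggle",
                    swim = "reverse_swim",
                    reverse_swim = "swim",
                    stop("initial_coil commands have no reverse"))
  config$pattern <- flipped
  config$propagation_speed <- -config$propagation_speed
  if (flipped %in% c("struggle", "reverse_struggle"))
    generate_struggle(config) else generate_swim(config)
}

#' Generate a surrogate initial-coil command
#'
#' One long burst per motoneuron on the side opposite to stimulation, a
#' fixed 15 spikes per neuron, with near-zero longitudinal propagation
#' delay (<= 1 ms across the roster).
#'
#' @param config a [command_config()] (pattern `"initial_coil"`).
#' @param roster a [build_roster()] roster.
#' @param stimulated_side `"L"` or `"R"`; the burst occurs contralaterally.
#' @param n_spikes spikes per neuron (default 15).
#' @param max_spread_ms maximal onset spread across the roster (default
#'   1 ms).
#' @return a `spike_table` (active side only).
#' @export
generate_initial_coil <- function(config = command_config("initial_coil"),
                                  roster = build_roster(),
                                  stimulated_side = "R",
                                  n_spikes = 15, max_spread_ms = 1) {
  stopifnot(inherits(config, "command_config"))
  active <- if (stimulated_side == "R") "L" else "R"
  sub <- roster[roster$side == active, ]
  sub <- sub[order(sub$position_mm, sub$id), ]
  pos_range <- range(sub$position_mm)
  span <- diff(pos_range)
  rows <- with_seed(config$seed, {
    out <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      p <- sub$position_mm[i]
      onset <- if (span > 0)
        (pos_range[2] - p) / span * max_spread_ms else 0
      isis <- as.numeric(stats::quantile(config$isi_source$rostral,
                                         stats::runif(n_spikes - 1),
                                         type = 7, names = FALSE))
      out[[i]] <- data.frame(neuron_id = sub$id[i], side = active,
                             position_mm = p,
                             spike_time_ms = onset + c(0, cumsum(isis)))
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  attr(rows, "config") <- config
  attr(rows, "stimulated_side") <- stimulated_side
  class(rows) <- c("spike_table", "data.frame")
  rows
}

#' Per-neuron burst statistics of a command
#'
#' Groups each neuron's spikes into bursts with [group_bursts()] and
#' returns per-neuron burst frequency, duty cycle and burst centre times —
#' the loop-closure between the generator and the rhythm-analysis module.
#'
#' @param table a `spike_table`.
#' @param positions optional `c(min, max)` position filter in mm.
#' @param side optional side filter.
#' @param max_gap burst-merge gap in ms; default: half the cycle period,
#'   capped at 50 ms (surrogate intra-burst ISIs are bounded by 13 ms).
#' @return data.frame with one row per neuron: `neuron_id`, `side`,
#'   `position_mm`, `frequency`, `duty_cycle`, `n_bursts`.
#' @export
command_burst_stats <- function(table, positions = NULL, side = NULL,
                                max_gap = NULL) {
  stopifnot(inherits(table, "spike_table"))
  if (is.null(max_gap)) max_gap <- default_merge_gap(table)
  d <- as.data.frame(table)
  if (!is.null(positions))
    d <- d[d$position_mm >= positions[1] & d$position_mm <= positions[2], ]
  if (!is.null(side)) d <- d[d$side == side, ]
  keys <- unique(d[, c("neuron_id", "side")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$neuron_id == keys$neuron_id[i] & d$side == keys$side[i], ]
    gb <- group_bursts(sort(sub$spike_time_ms) / 1000, max_gap = max_gap)
    data.frame(neuron_id = keys$neuron_id[i], side = keys$side[i],
               position_mm = sub$position_mm[1],
               frequency = gb$stats$frequency,
               duty_cycle = gb$stats$duty_cycle,
               n_bursts = gb$stats$n_bursts)
  })
  do.call(rbind, out)
}

#' Population burst statistics at a recording position
#'
#' Emulates a ventral-root electrode: pools the spikes of every neuron of
#' one side within a position window, groups the pooled events into bursts
#' and returns the rhythm statistics — the quantity the duty-cycle profile
#' of the generator is defined on (individual neurons fire shorter bursts
#' scattered within the population burst window).
#'
#' @param table a `spike_table`.
#' @param position window centre, mm.
#' @param width window width, mm (default 0.5).
#' @param side side to pool (default `"L"`).
#' @param max_gap burst-merge gap in ms (default 20).
#' @return the `stats` list of [group_bursts()].
#' @export
command_population_stats <- function(table, position, width = 0.5,
                                     side = "L", max_gap = 20) {
  stopifnot(inherits(table, "spike_table"))
  d <- as.data.frame(table)
  sel <- d$side == side & abs(d$position_mm - position) <= width / 2
  group_bursts(sort(d$spike_time_ms[sel]) / 1000,
               max_gap = max_gap)$stats
}

#' Longitudinal propagation speed of a command
#'
#' For each cycle on each side, per-neuron burst-centre times (midpoint of
#' first and last spike of the cycle's burst; for swimming, the single
#' spike) are regressed against rostrocaudal position; the speed is the
#' negated inverse slope, signed positive for caudorostral propagation.
#' Burst-to-cycle assignment is by per-neuron burst rank.
#'
#' @param table a `spike_table`.
#' @param max_gap burst-merge gap in ms; default: half the cycle period,
#'   capped at 50 ms.
#' @return list with `speed` (mm/s, mean over cycles; positive =
#'   caudorostral), `per_cycle` speeds, `n_cycles`.
#' @export
command_propagation_speed <- function(table, max_gap = NULL) {
  stopifnot(inherits(table, "spike_table"))
  if (is.null(max_gap)) max_gap <- default_merge_gap(table)
  d <- as.data.frame(table)
  recs <- list()
  for (side in unique(d$side)) {
    ds <- d[d$side == side, ]
    for (id in unique(ds$neuron_id)) {
      st <- sort(ds$spike_time_ms[ds$neuron_id == id])
      gb <- group_bursts(st / 1000, max_gap = max_gap)$bursts
      if (!nrow(gb)) next
      recs[[length(recs) + 1L]] <- data.frame(
        side = side, position_mm = ds$position_mm[ds$neuron_id == id][1],
        cycle = seq_len(nrow(gb)),
        centre_ms = (gb$start + gb$end) / 2 * 1000)
    }
  }
  recs <- do.call(rbind, recs)
  speeds <- c()
  for (side in unique(recs$side)) {
    for (cyc in unique(recs$cycle[recs$side == side])) {
      sub <- recs[recs$side == side & recs$cycle == cyc, ]
      if (nrow(sub) < 3 || stats::sd(sub$position_mm) == 0) next
      slope <- stats::coef(stats::lm(centre_ms ~ position_mm,
                                     data = sub))[[2]]   # ms per mm
      if (is.finite(slope) && slope != 0)
        speeds <- c(speeds, -1000 / slope)
    }
  }
  list(speed = mean(speeds), per_cycle = speeds,
       n_cycles = length(speeds))
}

#' Write / read a spike table
#'
#' TSV with columns `neuron_id`, `side`, `position_mm`, `spike_time_ms`
#' (times printed at 1e-6 ms precision) plus a JSON metadata sidecar
#' (`<path>.json`) echoing the generating configuration and seed.
#'
#' @param table a `spike_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(table, path) {
  d <- as.data.frame(table)
  d$spike_time_ms <- sprintf("%.6f", d$spike_time_ms)
  d$position_mm <- sprintf("%.6f", d$position_mm)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    meta <- cfg[setdiff(names(cfg), "isi_source")]
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "character", "numeric",
                                        "numeric"))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(d, "config") <- meta
  }
  class(d) <- c("spike_table", "data.frame")
  d
}
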