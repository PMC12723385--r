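#' Tracked tadpole midline
#'
#' Container for a pose-tracked tadpole midline: 11 ordered points per frame
#' (head `p1` to tail tip `p11`), uniform frame times, and body geometry.
#' Point coordinates are in mm in the tracking plane; a third (z) coordinate
#' is optional and treated as 0 when absent.
#'
#' @param points numeric array `frames x 11 x 2` (or `x 3`) of coordinates in
#'   mm, ordered head to tail along the second dimension.
#' @param frame_rate sampling rate of the video in Hz.
#' @param body_length body length in mm (default 5, stage 37/38 tadpole).
#' @param times optional frame times in seconds; defaults to
#'   `(0:(n-1))/frame_rate`. Must be uniform to within one sample.
#'
#' @return An object of class `tracked_body` with elements `times`, `points`,
#'   `frame_rate`, `body_length` and `point_spacing` (= body_length/10,
#'   equidistant vertices assumed).
#' @export
tracked_body <- function(points, frame_rate, body_length = 5, times = NULL) {
  if (length(dim(points)) != 3L)
    stop("`points` must be a frames x 11 x 2|3 array")
  if (dim(points)[2] != 11L)
    stop("exactly 11 points per frame are required (head p1 to tail tip p11)")
  if (!dim(points)[3] %in% c(2L, 3L))
    stop("points must have 2 or 3 coordinates")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0")
  n <- dim(points)[1]
  if (is.null(times)) times <- (seq_len(n) - 1) / frame_rate
  if (length(times) != n) stop("times must have one entry per frame")
  dt <- diff(times)
  if (n > 1 && (any(dt <= 0) ||
                max(abs(dt - 1 / frame_rate)) > 1 / frame_rate))
    stop("times must be strictly increasing and uniform at frame_rate")
  structure(
    list(times = times, points = points, frame_rate = frame_rate,
         body_length = body_length, point_spacing = body_length / 10),
    class = "tracked_body")
}

#' @export
print.tracked_body <- function(x, ...) {
  cat(sprintf("<tracked_body> %d frames @ %g fps, body %g mm (%dD)\n",
              dim(x$points)[1], x$frame_rate, x$body_length,
              dim(x$points)[3]))
  invisible(x)
}

#' Positions of the nine curvature-angle vertices along the body
#'
#' Vertices sit at the interior tracked points p2..p10, i.e. at fractions
#' 0.1 to 0.9 of body length from the head (equidistance assumed).
#'
#' @param body a [tracked_body()].
#' @return numeric vector of 9 positions in mm from the head.
#' @export
vertex_positions <- function(body) {
  (1:9) / 10 * body$body_length
}

#' Fill short tracking gaps by linear interpolation
#'
#' Missing samples (NA coordinates, e.g. masked low-likelihood points) are
#' linearly interpolated when a gap spans at most `max_gap` consecutive
#' frames; longer gaps are left as NA and excluded downstream.
#'
#' @param body a [tracked_body()] possibly containing NA coordinates.
#' @param max_gap longest run of consecutive missing frames to bridge
#'   (default 3).
#' @return a [tracked_body()] with short gaps filled.
#' @export
interpolate_gaps <- function(body, max_gap = 3) {
  pts <- body$points
  n <- dim(pts)[1]
  for (p in seq_len(dim(pts)[2])) {
    for (d in seq_len(dim(pts)[3])) {
      v <- pts[, p, d]
      if (!anyNA(v) || all(is.na(v))) next
      r <- rle(is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      ok <- !is.na(v)
      filled <- stats::approx(which(ok), v[ok], xout = seq_len(n),
                              rule = 1)$y
      for (k in seq_along(r$values)) {
        if (r$values[k] && r$lengths[k] <= max_gap)
          v[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
      }
      pts[, p, d] <- v
    }
  }
  body$points <- pts
  body
}

#' Read pose-tracked midline coordinates
#'
#' Supports two dialects: the pose-estimation CSV with three header rows
#' (`scorer` / `bodyparts` / `coords`, one `x`, `y` and optional `likelihood`
#' column per body part) and a plain TSV with columns
#' `time, x1, y1, ..., x11, y11`. Body parts are matched by name so column
#' order does not matter; points with likelihood below `likelihood_cutoff`
#' are masked to NA and later bridged by [interpolate_gaps()].
#'
#' @param path file to read.
#' @param dialect `"three_header_row"` or `"plain_tsv"`.
#' @param frame_rate video frame rate in Hz (required for the three-header
#'   dialect, which carries frame indices only).
#' @param body_length body length in mm.
#' @param bodyparts character vector of the 11 body-part names in
#'   head-to-tail order; defaults to `p1`..`p11`.
#' @param likelihood_cutoff samples with tracking likelihood below this are
#'   masked (default 0.9).
#' @return a [tracked_body()].
#' @export
read_pose_csv <- function(path,
                          dialect = c("three_header_row", "plain_tsv"),
                          frame_rate = 240, body_length = 5,
                          bodyparts = paste0("p", 1:11),
                          likelihood_cutoff = 0.9) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plain_tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t")
    need <- c("time", paste0(rep(c("x", "y"), 11), rep(1:11, each = 2)))
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    n <- nrow(d)
    pts <- array(NA_real_, c(n, 11, 2))
    for (i in 1:11) {
      pts[, i, 1] <- as.numeric(d[[paste0("x", i)]])
      pts[, i, 2] <- as.numeric(d[[paste0("y", i)]])
    }
    dt <- stats::median(diff(d$time))
    return(tracked_body(pts, frame_rate = 1 / dt, body_length = body_length,
                        times = d$time))
  }
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  dat <- utils::read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  miss <- setdiff(bodyparts, unique(parts))
  if (length(miss))
    stop("body parts missing from header: ", paste(miss, collapse = ", "))
  n <- nrow(dat)
  pts <- array(NA_real_, c(n, 11, 2))
  for (i in seq_along(bodyparts)) {
    xi <- which(parts == bodyparts[i] & coords == "x") + 1L
    yi <- which(parts == bodyparts[i] & coords == "y") + 1L
    li <- which(parts == bodyparts[i] & coords == "likelihood") + 1L
    x <- suppressWarnings(as.numeric(dat[[xi[1]]]))
    y <- suppressWarnings(as.numeric(dat[[yi[1]]]))
    bad_cells <- which(is.na(x) & !is.na(dat[[xi[1]]]) & dat[[xi[1]]] != "")
    if (length(bad_cells))
      stop("non-numeric cell(s) for ", bodyparts[i], " at data row(s) ",
           paste(utils::head(bad_cells, 5), collapse = ", "))
    if (length(li)) {
      lk <- suppressWarnings(as.numeric(dat[[li[1]]]))
      mask <- !is.na(lk) & lk < likelihood_cutoff
      x[mask] <- NA_real_
      y[mask] <- NA_real_
    }
    pts[, i, 1] <- x
    pts[, i, 2] <- y
  }
  interpolate_gaps(tracked_body(pts, frame_rate = frame_rate,
                                body_length = body_length))
}

#' Write a tracked midline as plain TSV
#'
#' Inverse of [read_pose_csv()] with `dialect = "plain_tsv"`.
#'
#' @param body a [tracked_body()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pose_tsv <- function(body, path) {
  n <- dim(body$points)[1]
  d <- data.frame(time = body$times)
  for (i in 1:11) {
    d[[paste0("x", i)]] <- body$points[, i, 1]
    d[[paste0("y", i)]] <- body$points[, i, 2]
  }
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
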