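#' Center of pressure of one frame
#'
#' The COP is the centroid of the vertical pressure distribution: the
#' pressure-weighted mean of the active cell centers. Binary recordings
#' (all pressures equal) reduce to the geometric centroid.
#'
#' @param cells data.frame with `row`, `col`, `pressure` for one frame.
#' @param cell_pitch cell spacing in mm.
#' @return Named vector `c(a, b)` in mm, or `NULL` when the total pressure
#'   is zero (no COP sample for that frame).
#' @export
cop_of_frame <- function(cells, cell_pitch) {
  w <- cells$pressure
  tot <- sum(w)
  if (!nrow(cells) || tot <= 0) return(NULL)
  P <- cell_center(cells$row, cells$col, cell_pitch)
  c(a = sum(P[, 1] * w) / tot, b = sum(P[, 2] * w) / tot)
}

#' Build the foot-frame COP trajectory of a footfall
#'
#' For every frame between first and last contact in which the footfall has
#' active cells with positive total pressure, the mat-frame COP is the
#' pressure-weighted centroid of those cells; each sample is then converted
#' into the foot frame with [transform_point()] (origin at the heel center,
#' y along the foot axis, x mirrored for left feet so +x is always
#' medial-to-lateral).
#'
#' @param ff a `footfall` (its `frames` field supplies per-frame pressures).
#' @param axis the matching [estimate_axis()] result.
#' @param side `"right"`, `"left"` or `"unknown"`; defaults to the
#'   footfall's own label.
#' @return Object of class `cop_trajectory`: data.frame with columns
#'   `time_ms`, `a`, `b` (mat frame, mm), `x`, `y` (foot frame, mm);
#'   attributes `side`, `index`, `foot_length`, `foot_width`. Errors if
#'   fewer than two frames yield a COP sample.
#' @export
build_trajectory <- function(ff, axis, side = NULL) {
  side <- side %||% ff$side
  fr <- ff$frames
  if (is.null(fr) || !nrow(fr))
    stop("footfall ", ff$index %||% "?", " has no per-frame samples")
  ms <- 1000 / ff$sampling_rate
  cops <- lapply(split(fr, fr$frame), cop_of_frame, cell_pitch = ff$cell_pitch)
  keep <- !vapply(cops, is.null, TRUE)
  if (sum(keep) < 2)
    stop("footfall ", ff$index %||% "?",
         ": fewer than 2 frames with a COP sample")
  raw <- do.call(rbind, cops[keep])
  times <- as.numeric(names(cops))[keep] * ms
  ord <- order(times)
  raw <- raw[ord, , drop = FALSE]
  times <- times[ord]
  xy <- transform_point(raw, axis, side)
  out <- data.frame(time_ms = times, a = raw[, 1], b = raw[, 2],
                    x = xy[, 1], y = xy[, 2])
  rownames(out) <- NULL
  structure(out, side = side, index = ff$index,
            foot_length = axis$foot_length, foot_width = axis$foot_width,
            class = c("cop_trajectory", "data.frame"))
}

traj_window <- function(traj, interval) {
  traj[traj$time_ms >= interval[1] & traj$time_ms <= interval[2], ,
       drop = FALSE]
}

#' COP displacement range within an interval
#'
#' Max minus min of the mediolateral (`x`) or anteroposterior (`y`)
#' foot-frame coordinate over the samples falling in the closed interval.
#'
#' @param traj a [build_trajectory()] result.
#' @param interval numeric length-2, `c(start_ms, end_ms)`.
#' @param axis `"ML"` or `"AP"`.
#' @return Range in mm; `NA` when the interval holds no sample.
#' @export
displacement_range <- function(traj, interval, axis = c("ML", "AP")) {
  axis <- match.arg(axis)
  w <- traj_window(traj, interval)
  if (!nrow(w)) return(NA_real_)
  v <- if (axis == "ML") w$x else w$y
  max(v) - min(v)
}

#' Mean COP location within an interval, as a percentage of foot size
#'
#' Mediolateral locations are normalized by foot width, anteroposterior
#' locations by foot length. The sign is preserved: the origin is the heel
#' center, so the COP can sit behind it (negative y early in stance) or
#' medial to the axis (negative x).
#'
#' @inheritParams displacement_range
#' @param foot_length,foot_width mm; default from the trajectory.
#' @return Mean location in \%, or `NA` for an empty interval.
#' @export
mean_location <- function(traj, interval, axis = c("ML", "AP"),
                          foot_length = attr(traj, "foot_length"),
                          foot_width = attr(traj, "foot_width")) {
  axis <- match.arg(axis)
  w <- traj_window(traj, interval)
  if (!nrow(w)) return(NA_real_)
  if (axis == "ML") {
    stopifnot(foot_width > 0)
    100 * mean(w$x) / foot_width
  } else {
    stopifnot(foot_length > 0)
    100 * mean(w$y) / foot_length
  }
}

#' COP velocity within an interval
#'
#' By default the path-length definition: the summed absolute
#' frame-to-frame increments of the chosen coordinate (or the Euclidean
#' path for `"total"`), divided by the interval duration. An increment
#' between consecutive samples is attributed to the interval that contains
#' the pair's later sample, so adjacent subphases share boundary samples
#' but never double-count increments. `definition = "net"` instead uses the
#' displacement between the first and last sample in the interval.
#'
#' @inheritParams displacement_range
#' @param axis `"ML"`, `"AP"` or `"total"`.
#' @param definition `"path"` (default) or `"net"`.
#' @return Velocity in cm/s; `NA` with fewer than 2 samples in the interval.
#' @export
velocity <- function(traj, interval, axis = c("ML", "AP", "total"),
                     definition = c("path", "net")) {
  axis <- match.arg(axis)
  definition <- match.arg(definition)
  dur <- interval[2] - interval[1]
  if (!isTRUE(dur > 0)) return(NA_real_)
  if (sum(traj$time_ms >= interval[1] & traj$time_ms <= interval[2]) < 2)
    return(NA_real_)
  if (definition == "net") {
    w <- traj_window(traj, interval)
    len <- switch(axis,
                  ML = abs(w$x[nrow(w)] - w$x[1]),
                  AP = abs(w$y[nrow(w)] - w$y[1]),
                  total = sqrt((w$x[nrow(w)] - w$x[1])^2 +
                                 (w$y[nrow(w)] - w$y[1])^2))
  } else {
    n <- nrow(traj)
    later <- traj$time_ms[-1]
    use <- later > interval[1] & later <= interval[2]
    dx <- diff(traj$x)[use]
    dy <- diff(traj$y)[use]
    len <- switch(axis,
                  ML = sum(abs(dx)),
                  AP = sum(abs(dy)),
                  total = sum(sqrt(dx^2 + dy^2)))
  }
  # mm/ms == m/s; report cm/s
  100 * len / dur
}

#' Resample a COP trajectory at equally spaced percentages of stance
#'
#' Linear interpolation of the foot-frame coordinates at `n_points` equally
#' spaced stance percentages (0 to 100), optionally normalized by foot
#' width and length so cohorts with different foot sizes can be averaged
#' into a mean trajectory band.
#'
#' @param traj a [build_trajectory()] result (>= 2 samples).
#' @param n_points number of resampled points, default 100.
#' @param normalize if `TRUE`, express `x` as \% of `foot_width` and `y` as
#'   \% of `foot_length`.
#' @param foot_length,foot_width mm; default from the trajectory. Supply
#'   cohort averages to reproduce a cohort-normalized band.
#' @return data.frame with columns `pct`, `x`, `y`.
#' @export
resample_trajectory <- function(traj, n_points = 100, normalize = FALSE,
                                foot_length = attr(traj, "foot_length"),
                                foot_width = attr(traj, "foot_width")) {
  if (nrow(traj) < 2) stop("need at least 2 samples to resample")
  pct <- seq(0, 100, length.out = n_points)
  t0 <- min(traj$time_ms); t1 <- max(traj$time_ms)
  tt <- t0 + pct / 100 * (t1 - t0)
  x <- stats::approx(traj$time_ms, traj$x, xout = tt, ties = "ordered")$y
  y <- stats::approx(traj$time_ms, traj$y, xout = tt, ties = "ordered")$y
  if (normalize) {
    stopifnot(foot_width > 0, foot_length > 0)
    x <- 100 * x / foot_width
    y <- 100 * y / foot_length
  }
  data.frame(pct = pct, x = x, y = y)
}
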