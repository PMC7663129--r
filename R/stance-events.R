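#' Detect stance-phase time points from per-cell activation times
#'
#' The six stance events are defined on the footfall's per-cell
#' first-activation and last-deactivation times and the proximal / middle /
#' distal thirds of the foot:
#' \describe{
#'   \item{FCT}{first contact time: earliest activation over all cells.}
#'   \item{MON}{midfoot-on: earliest activation among middle-third cells.}
#'   \item{FFT}{foot flat: earliest time by which 78\% of all cells
#'     associated with the foot have been activated, i.e. the
#'     `ceiling(0.78 * N)`-th distinct activation.}
#'   \item{HOT}{heel-off: last deactivation among proximal-third cells.}
#'   \item{MOF}{midfoot-off: last deactivation among middle-third cells.}
#'   \item{LCT}{last contact time: latest deactivation over all cells.}
#' }
#' Events are reported at frame resolution (multiples of the frame period).
#' A footfall whose events are not in the order FCT <= MON <= FFT <= HOT <=
#' MOF <= LCT is flagged invalid (`valid = FALSE`) and should be excluded
#' from parameter tables; [analyze_recording()] does this and logs the
#' reason.
#'
#' @param ff a `footfall`.
#' @param axis the matching [estimate_axis()] result (supplies the thirds).
#' @param fft_rule `"cumulative"` (default): FFT counts distinct cells ever
#'   activated. `"concurrent"`: FFT is the earliest time at which at least
#'   78\% of the cells are simultaneously active (using each cell's
#'   first-on / last-off interval).
#' @param fft_fraction threshold fraction of cells, default 0.78.
#' @return Object of class `stance_events`: list with the six event times in
#'   ms, `stance_ms`, `valid`, and (after [normalize_events()]) the events
#'   as percentages of stance.
#' @export
detect_events <- function(ff, axis, fft_rule = c("cumulative", "concurrent"),
                          fft_fraction = 0.78) {
  fft_rule <- match.arg(fft_rule)
  cells <- ff$cells
  thirds <- axis$thirds
  stopifnot(length(thirds) == nrow(cells))
  for (th in 1:3) {
    if (!any(thirds == th))
      stop("footfall ", ff$index %||% "?", ": empty third ", th)
  }
  n <- nrow(cells)
  need <- ceiling(fft_fraction * n)
  fct <- min(cells$t_on_ms)
  lct <- max(cells$t_off_ms)
  mon <- min(cells$t_on_ms[thirds == 2])
  hot <- max(cells$t_off_ms[thirds == 1])
  mof <- max(cells$t_off_ms[thirds == 2])
  if (fft_rule == "cumulative") {
    fft <- sort(cells$t_on_ms)[need]
  } else {
    cand <- sort(unique(cells$t_on_ms))
    nact <- vapply(cand, function(t) {
      sum(cells$t_on_ms <= t & cells$t_off_ms >= t)
    }, 0L)
    hit <- which(nact >= need)
    fft <- if (length(hit)) cand[hit[1]] else NA_real_
  }
  ev <- c(FCT = fct, MON = mon, FFT = fft, HOT = hot, MOF = mof, LCT = lct)
  valid <- !anyNA(ev) && !is.unsorted(ev) && lct > fct
  structure(list(FCT = fct, MON = mon, FFT = fft, HOT = hot,
                 MOF = mof, LCT = lct,
                 stance_ms = lct - fct, valid = valid),
            class = "stance_events")
}

#' @export
print.stance_events <- function(x, ...) {
  cat(sprintf(
    "<stance_events%s> FCT=%.1f MON=%.1f FFT=%.1f HOT=%.1f MOF=%.1f LCT=%.1f ms (stance %.1f ms)\n",
    if (x$valid) "" else " INVALID", x$FCT, x$MON, x$FFT, x$HOT, x$MOF,
    x$LCT, x$stance_ms))
  invisible(x)
}

#' Normalize stance events to percentages of stance duration
#'
#' Each event time `t` becomes `100 * (t - FCT) / (LCT - FCT)`, so FCT maps
#' to 0 and LCT to 100.
#'
#' @param ev a [detect_events()] result.
#' @return `ev` with an added `pct` named vector (FCT, MON, FFT, HOT, MOF,
#'   LCT as \% of stance).
#' @export
normalize_events <- function(ev) {
  stopifnot(inherits(ev, "stance_events"))
  if (!isTRUE(ev$stance_ms > 0)) stop("stance duration must be > 0")
  t <- c(FCT = ev$FCT, MON = ev$MON, FFT = ev$FFT, HOT = ev$HOT,
         MOF = ev$MOF, LCT = ev$LCT)
  ev$pct <- 100 * (t - ev$FCT) / ev$stance_ms
  ev
}

#' Build the stance subphase intervals from the event times
#'
#' The five primary subphases tile the stance phase: initial contact
#' ICP = \[FCT, MON\], late contact LCP = \[MON, FFT\], foot flat
#' FFP = \[FFT, HOT\], initial propulsive IPP = \[HOT, MOF\] and late
#' propulsive LPP = \[MOF, LCT\]. CbP = \[MON, HOT\] combines LCP and FFP,
#' whose boundary (FFT) is the most variable event. Their percentage
#' durations telescope to exactly 100 (CbP excluded).
#'
#' @param ev a valid [detect_events()] result.
#' @return Object of class `subphase_set`: named list of subphases, each
#'   `list(start_ms, end_ms, dur_ms, dur_pct)`, plus `stance_ms`.
#' @export
build_subphases <- function(ev) {
  stopifnot(inherits(ev, "stance_events"))
  if (!isTRUE(ev$valid)) stop("cannot build subphases from invalid events")
  bounds <- list(ICP = c(ev$FCT, ev$MON), LCP = c(ev$MON, ev$FFT),
                 FFP = c(ev$FFT, ev$HOT), CbP = c(ev$MON, ev$HOT),
                 IPP = c(ev$HOT, ev$MOF), LPP = c(ev$MOF, ev$LCT))
  out <- lapply(bounds, function(bd) {
    list(start_ms = bd[1], end_ms = bd[2], dur_ms = bd[2] - bd[1],
         dur_pct = 100 * (bd[2] - bd[1]) / ev$stance_ms)
  })
  out$stance_ms <- ev$stance_ms
  class(out) <- "subphase_set"
  out
}

#' Names of the subphases, in stance order (CbP after FFP)
#' @return Character vector `c("ICP","LCP","FFP","CbP","IPP","LPP")`.
#' @export
subphase_names <- function() c("ICP", "LCP", "FFP", "CbP", "IPP", "LPP")
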