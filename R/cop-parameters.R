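#' Full COP parameter set for one footfall
#'
#' Combines the temporal, spatial and velocity parameters of a single
#' footfall into one wide row: stance duration, the four normalized time
#' points, and per subphase (ICP, LCP, FFP, CbP, IPP, LPP) the percentage
#' duration, mediolateral/anteroposterior displacement ranges (mm), mean
#' locations (\% of foot width / length) and velocities (cm/s). Empty
#' subphases (possible when two events coincide at frame resolution) yield
#' `NA`, never zero.
#'
#' @param traj a [build_trajectory()] result.
#' @param ev valid, normalized [detect_events()] result.
#' @param subphases matching [build_subphases()] result (built from `ev`
#'   when omitted).
#' @param velocity_def passed to [velocity()] as `definition`.
#' @return One-row data.frame with columns `stance_ms`, `MON_pct`,
#'   `FFT_pct`, `HOT_pct`, `MOF_pct`, then
#'   `<subphase>_{dur_pct,rangeML_mm,rangeAP_mm,mlocML_pct,mlocAP_pct,velML_cms,velAP_cms,velTot_cms}`.
#' @export
footfall_parameters <- function(traj, ev, subphases = NULL,
                                velocity_def = c("path", "net")) {
  velocity_def <- match.arg(velocity_def)
  if (is.null(ev$pct)) ev <- normalize_events(ev)
  subphases <- subphases %||% build_subphases(ev)
  row <- data.frame(stance_ms = ev$stance_ms,
                    MON_pct = ev$pct[["MON"]], FFT_pct = ev$pct[["FFT"]],
                    HOT_pct = ev$pct[["HOT"]], MOF_pct = ev$pct[["MOF"]])
  for (sp in subphase_names()) {
    iv <- c(subphases[[sp]]$start_ms, subphases[[sp]]$end_ms)
    row[[paste0(sp, "_dur_pct")]] <- subphases[[sp]]$dur_pct
    row[[paste0(sp, "_rangeML_mm")]] <- displacement_range(traj, iv, "ML")
    row[[paste0(sp, "_rangeAP_mm")]] <- displacement_range(traj, iv, "AP")
    row[[paste0(sp, "_mlocML_pct")]] <- mean_location(traj, iv, "ML")
    row[[paste0(sp, "_mlocAP_pct")]] <- mean_location(traj, iv, "AP")
    row[[paste0(sp, "_velML_cms")]] <- velocity(traj, iv, "ML", velocity_def)
    row[[paste0(sp, "_velAP_cms")]] <- velocity(traj, iv, "AP", velocity_def)
    row[[paste0(sp, "_velTot_cms")]] <- velocity(traj, iv, "total", velocity_def)
  }
  row
}

#' Analyze one mat recording end to end
#'
#' Runs the full measurement pipeline on a recording: footfall detection,
#' side assignment, foot-axis estimation, stance-event detection, COP
#' trajectory construction and parameterization. Footfalls that fail a step
#' (degenerate geometry, empty third, non-monotone events, too few COP
#' samples) are excluded, not repaired; the exclusions with their reasons
#' are attached as the `"exclusions"` attribute.
#'
#' @param rec a [mat_recording()].
#' @param subject,condition labels copied into every output row.
#' @param min_cells,max_gap passed to [detect_footfalls()].
#' @param fft_rule,fft_fraction passed to [detect_events()].
#' @param velocity_def passed to [footfall_parameters()].
#' @return data.frame with one row per valid footfall: `subject`,
#'   `condition`, `side`, `footfall` (order of first contact),
#'   `first_contact_ms`, `theta_c_deg`, `foot_length_mm`, `foot_width_mm`,
#'   then all [footfall_parameters()] columns. Attribute `"exclusions"`:
#'   data.frame `footfall`, `reason`.
#' @export
analyze_recording <- function(rec, subject = NA, condition = NA,
                              min_cells = 5, max_gap = 2,
                              fft_rule = "cumulative", fft_fraction = 0.78,
                              velocity_def = "path") {
  ffs <- assign_sides(detect_footfalls(rec, min_cells, max_gap))
  rows <- list()
  excl <- list()
  for (ff in ffs) {
    res <- tryCatch({
      axis <- estimate_axis(ff)
      ev <- detect_events(ff, axis, fft_rule = fft_rule,
                          fft_fraction = fft_fraction)
      if (!ev$valid) stop("non-monotone stance events")
      ev <- normalize_events(ev)
      traj <- build_trajectory(ff, axis)
      pars <- footfall_parameters(traj, ev, velocity_def = velocity_def)
      cbind(data.frame(subject = subject, condition = condition,
                       side = ff$side, footfall = ff$index,
                       first_contact_ms = ff$t_first_ms,
                       theta_c_deg = axis$theta_c * 180 / pi,
                       foot_length_mm = axis$foot_length,
                       foot_width_mm = axis$foot_width),
            pars)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1]] <- data.frame(footfall = ff$index,
                                             reason = res)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_parameter_table(subject, condition)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(footfall = integer(), reason = character())
  out
}

empty_parameter_table <- function(subject = NA, condition = NA) {
  base <- data.frame(subject = character(), condition = character(),
                     side = character(), footfall = integer(),
                     first_contact_ms = numeric(), theta_c_deg = numeric(),
                     foot_length_mm = numeric(), foot_width_mm = numeric(),
                     stance_ms = numeric(), MON_pct = numeric(),
                     FFT_pct = numeric(), HOT_pct = numeric(),
                     MOF_pct = numeric())
  for (sp in subphase_names()) {
    for (m in c("dur_pct", "rangeML_mm", "rangeAP_mm", "mlocML_pct",
                "mlocAP_pct", "velML_cms", "velAP_cms", "velTot_cms")) {
      base[[paste0(sp, "_", m)]] <- numeric()
    }
  }
  base
}

#' Build a parameter table across recordings
#'
#' Applies [analyze_recording()] to a list of recordings (e.g. the passes
#' of every subject and condition) and stacks the rows, renumbering
#' footfalls consecutively within each subject/condition/side so the
#' footfall column is the measurement-repetition index used by the
#' reliability analysis.
#'
#' @param recordings list of [mat_recording()] objects.
#' @param subject,condition vectors recycled along `recordings`.
#' @param ... passed to [analyze_recording()].
#' @return data.frame as in [analyze_recording()]; attribute `"exclusions"`
#'   gains `subject` and `condition` columns.
#' @export
parameter_table <- function(recordings, subject = NA, condition = NA, ...) {
  n <- length(recordings)
  subject <- rep_len(subject, n)
  condition <- rep_len(condition, n)
  tabs <- vector("list", n)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    tabs[[i]] <- analyze_recording(recordings[[i]], subject = subject[i],
                                   condition = condition[i], ...)
    ei <- attr(tabs[[i]], "exclusions")
    if (nrow(ei)) {
      ei$subject <- subject[i]
      ei$condition <- condition[i]
      excl[[i]] <- ei
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (nrow(out)) {
    grp <- interaction(out$subject, out$condition, out$side, drop = TRUE)
    out <- out[order(grp, out$first_contact_ms), ]
    out$footfall <- stats::ave(seq_len(nrow(out)),
                               interaction(out$subject, out$condition,
                                           out$side, drop = TRUE),
                               FUN = seq_along)
    out <- out[order(out$subject, out$condition, out$side, out$footfall), ]
    rownames(out) <- NULL
  }
  attr(out, "exclusions") <- do.call(rbind, excl[!vapply(excl, is.null, TRUE)])
  out
}
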