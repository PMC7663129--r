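#' Configuration for the synthetic gait generator
#'
#' Bundles the study-design quantities the generator emulates: mat geometry
#' (sampling rate 240 Hz, 12.7 mm pitch), cohort anthropometrics (foot
#' length 240.1 (17.3) mm, width 100.1 (9.9) mm), pace-dependent gait
#' (walking speed, cadence, stance duration with between- and
#' within-subject components), and the rollover timing targets: the mean
#' stance-phase percentages of the four events (MON, FFT, HOT, MOF) with
#' between-subject and within-subject (footfall-to-footfall) SDs. Defaults
#' follow the reference values for healthy young adults at the chosen pace.
#'
#' @param seed integer seed; every generator call that receives a config
#'   with a non-NULL seed is deterministic.
#' @param pace `"comfortable"` or `"fast"`; presets speed, cadence and
#'   stance duration.
#' @param n_subjects,footfalls_per_side cohort size for
#'   [generate_cohort()].
#' @param n_steps footfalls per recording (one walkway pass).
#' @param grid_rows,grid_cols,cell_pitch,sampling_rate mat geometry.
#' @param foot_length,foot_width mm, `c(mean, sd)` between subjects.
#' @param speed cm/s `c(mean, sd)`; `cadence` steps/min `c(mean, sd)`.
#' @param stance ms `c(mean, between_sd, within_sd)`.
#' @param event_pct 4 x 3 matrix (rows MON, FFT, HOT, MOF; columns mean,
#'   between_sd, within_sd), percentages of stance.
#' @param heel_off_onset_pct stance percentage at which the earliest heel
#'   cell starts deactivating.
#' @param toe_out_deg out-toeing angle `c(mean, between_sd, within_sd)`,
#'   degrees; applied with opposite sign to left feet.
#' @param step_width_mm lateral distance between left and right foot
#'   centers.
#' @param ml_sway dimensionless amplitude of the mediolateral pressure
#'   modulation that drives COP sway (0 disables it).
#' @param fit_steps if `TRUE` (default), [generate_recording()] trims the
#'   steps per pass to what the mat length can hold for the subject's
#'   stride instead of erroring.
#' @param time_jitter_ms per-cell SD of activation/deactivation jitter.
#' @param dropout_rate probability that an individual cell-frame sample is
#'   lost.
#' @param placement_jitter_mm SD of footfall placement noise.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = NULL,
                         pace = c("comfortable", "fast"),
                         n_subjects = 5, footfalls_per_side = 7,
                         n_steps = 5,
                         grid_rows = 288, grid_cols = 48,
                         cell_pitch = 12.7, sampling_rate = 240,
                         foot_length = c(240.1, 17.3),
                         foot_width = c(100.1, 9.9),
                         speed = NULL, cadence = NULL, stance = NULL,
                         event_pct = NULL,
                         heel_off_onset_pct = 30,
                         toe_out_deg = c(5, 3, 1.5),
                         step_width_mm = 120,
                         ml_sway = 1.2,
                         fit_steps = TRUE,
                         time_jitter_ms = 2,
                         dropout_rate = 0.001,
                         placement_jitter_mm = 3) {
  pace <- match.arg(pace)
  if (is.null(speed)) speed <- if (pace == "comfortable") c(129, 16)
                               else c(161.8, 20.6)
  if (is.null(cadence)) cadence <- if (pace == "comfortable") c(118.3, 8)
                                   else c(134, 10.6)
  if (is.null(stance)) stance <- if (pace == "comfortable")
    c(613.7, 43.3, 16.7) else c(528.6, 43.5, 15.7)
  if (is.null(event_pct)) {
    event_pct <- if (pace == "comfortable") rbind(
      MON = c(8.83, 1.95, 1.00),
      FFT = c(40.85, 5.00, 5.40),
      HOT = c(59.32, 6.20, 3.40),
      MOF = c(87.02, 2.60, 2.30)
    ) else rbind(
      MON = c(9.71, 2.10, 1.25),
      FFT = c(40.90, 4.90, 5.45),
      HOT = c(54.11, 5.45, 3.05),
      MOF = c(83.48, 3.35, 3.00)
    )
    colnames(event_pct) <- c("mean", "between_sd", "within_sd")
  }
  cfg <- list(seed = seed, pace = pace, n_subjects = n_subjects,
              footfalls_per_side = footfalls_per_side, n_steps = n_steps,
              grid_rows = grid_rows, grid_cols = grid_cols,
              cell_pitch = cell_pitch, sampling_rate = sampling_rate,
              foot_length = foot_length, foot_width = foot_width,
              speed = speed, cadence = cadence, stance = stance,
              event_pct = event_pct,
              heel_off_onset_pct = heel_off_onset_pct,
              toe_out_deg = toe_out_deg, step_width_mm = step_width_mm,
              ml_sway = ml_sway, fit_steps = fit_steps,
              time_jitter_ms = time_jitter_ms,
              dropout_rate = dropout_rate,
              placement_jitter_mm = placement_jitter_mm)
  stopifnot(all(event_pct[, 2:3] >= 0), all(diff(event_pct[, 1]) > 0),
            event_pct[1, 1] > 0, event_pct[4, 1] < 100,
            n_subjects >= 1, footfalls_per_side >= 1, n_steps >= 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Zero-noise variant of a synthetic configuration
#'
#' Sets the sensor/timing noise sources (activation jitter, cell dropout,
#' placement jitter) to zero while keeping the biological between/within
#' variability, giving the noise-free oracle used by recovery tests.
#'
#' @param cfg a [synth_config()].
#' @return The config with noise terms zeroed.
#' @export
zero_noise <- function(cfg) {
  cfg$time_jitter_ms <- 0
  cfg$dropout_rate <- 0
  cfg$placement_jitter_mm <- 0
  cfg
}

# half-width outline of the sole as a fraction of (foot_width / 2),
# by normalized along-foot position s in [0, 1] (0 = heel, 1 = toe tip).
sole_halfwidth <- function(s) {
  knots_s <- c(0, 0.12, 0.30, 0.45, 0.62, 0.75, 0.90, 1)
  knots_w <- c(0.60, 0.78, 0.62, 0.55, 0.85, 1.00, 0.85, 0.55)
  stats::approx(knots_s, knots_w, xout = pmin(pmax(s, 0), 1))$y
}

# Smooth per-cell pressure: rise-fall over the cell's active interval
# modulated laterally to make the COP sway medially/laterally over stance.
# The weight vanishes continuously at activation and deactivation so the
# continuous-time COP has no jumps when cells switch on or off.
rollover_pressure <- function(tau, v_over_w, phase, ml_sway) {
  sin(pi * pmin(pmax(tau, 0), 1)) *
    (1 + ml_sway * v_over_w * sin(2 * pi * phase))
}

#' Generate one synthetic rollover footfall
#'
#' Rasterizes a foot-shaped outline onto the mat grid at a given position
#' and orientation and assigns each cell a continuous activation and
#' deactivation time following a heel-to-toe contact wave: activation time
#' grows monotonically with position along the foot axis, calibrated so
#' that the stance events land at the requested percentages of stance;
#' deactivation likewise (heel cells release first, toes last). Per-cell
#' pressure follows a smooth rise-fall profile. Ground-truth events are
#' computed from the continuous times with the same third-partition and
#' event rules the detector applies, and ground-truth parameters from a
#' densely sampled continuous COP trajectory, so the pipeline's only
#' expected deviation is the 240 Hz / 12.7 mm discretization.
#'
#' @param heel_a,heel_b mat-frame position of the heel end of the outline,
#'   mm.
#' @param theta_deg foot-axis angle from the mat's vertical axis, degrees
#'   (positive = toes toward +a).
#' @param side `"left"` or `"right"`.
#' @param foot_length,foot_width mm.
#' @param stance_ms stance duration.
#' @param t0_ms absolute time of first contact.
#' @param event_pct named numeric, target `MON`, `FFT`, `HOT`, `MOF`
#'   percentages of stance.
#' @param heel_off_onset_pct,ml_sway,time_jitter_ms,dropout_rate see
#'   [synth_config()].
#' @param cell_pitch,sampling_rate,grid_rows,grid_cols mat geometry.
#' @param toe_lag_pct stance percentage between foot-flat and the last toe
#'   activation.
#' @return List with `cells` (row, col, t_on_ms, t_off_ms), `frames`
#'   (frame, row, col, pressure) and `truth` (planted geometry, continuous
#'   events, dense trajectory, true parameter row).
#' @export
generate_footfall <- function(heel_a, heel_b, theta_deg, side,
                              foot_length, foot_width,
                              stance_ms, t0_ms = 0,
                              event_pct = c(MON = 8.83, FFT = 40.85,
                                            HOT = 59.32, MOF = 87.02),
                              heel_off_onset_pct = 30,
                              ml_sway = 1.2,
                              time_jitter_ms = 0, dropout_rate = 0,
                              cell_pitch = 12.7, sampling_rate = 240,
                              grid_rows = 288, grid_cols = 48,
                              toe_lag_pct = 5) {
  theta <- theta_deg * pi / 180
  dvec <- c(sin(theta), cos(theta))     # along foot, heel -> toe
  nvec <- c(cos(theta), -sin(theta))    # across foot

  # rasterize the outline onto the grid
  corners_u <- c(0, foot_length)
  ca <- heel_a + corners_u * dvec[1]
  cb <- heel_b + corners_u * dvec[2]
  half_max <- foot_width / 2
  b_span <- range(cb) + c(-half_max, half_max)
  a_span <- range(ca) + c(-half_max, half_max)
  if (b_span[1] < 0 || b_span[2] > grid_rows * cell_pitch ||
      a_span[1] < 0 || a_span[2] > grid_cols * cell_pitch)
    stop("footfall extends off the mat")
  rows <- floor(b_span / cell_pitch)
  cols <- floor(a_span / cell_pitch)
  grid <- expand.grid(row = max(0, rows[1]):min(grid_rows - 1, rows[2]),
                      col = max(0, cols[1]):min(grid_cols - 1, cols[2]))
  P <- cell_center(grid$row, grid$col, cell_pitch)
  u <- (P[, 1] - heel_a) * dvec[1] + (P[, 2] - heel_b) * dvec[2]
  v <- (P[, 1] - heel_a) * nvec[1] + (P[, 2] - heel_b) * nvec[2]
  inside <- u >= 0 & u <= foot_length &
    abs(v) <= sole_halfwidth(u / foot_length) * half_max
  if (sum(inside) < 9)
    stop("footfall outline rasterized to fewer than 9 cells")
  cells <- data.frame(row = grid$row[inside], col = grid$col[inside])

  # third partition and along/across coordinates via the same rules the
  # detector uses (shared code path)
  tmp <- list(cells = cells, index = NA_integer_, cell_pitch = cell_pitch,
              walking_axis = "+b", sampling_rate = sampling_rate)
  axis <- estimate_axis(tmp)
  Pc <- cell_center(cells$row, cells$col, cell_pitch)
  fc <- transform_point(Pc, axis, side = "right")
  proj <- fc[, "y"] + axis_proj_offset(axis)   # projection along l
  vx <- fc[, "x"]                              # signed across-axis offset

  # contact-wave timing, piecewise linear in the along-axis projection;
  # the wave advances one cross-band (one pitch) at a time, so cells of a
  # band share their activation/deactivation times and the sub-frame
  # lateral fill-in of a band cannot alias the mediolateral COP path
  proj_t <- min(proj) + cell_pitch * round((proj - min(proj)) / cell_pitch)
  lo <- min(proj_t); hi <- max(proj_t)
  q1 <- lo + (hi - lo) / 3
  q2 <- lo + 2 * (hi - lo) / 3
  n <- nrow(cells)
  u_fft <- max(sort(proj_t)[ceiling(0.78 * n)], q1 + 1e-6)
  ev <- event_pct
  # Rollover profiles live on a "model" stance clock. The heel lands as a
  # patch (flat activation over the rear tenth) and settles for a short
  # dwell before the roll starts; the toes release together after the
  # roll finishes a dwell before last contact.
  patch <- lo + 0.10 * (hi - lo)
  toe_patch <- hi - 0.10 * (hi - lo)
  u_fft <- min(max(u_fft, q1 + 1e-6), toe_patch)
  act_x <- c(lo, patch, q1, u_fft, hi)
  act_y <- c(0, 0, ev[["MON"]], ev[["FFT"]], ev[["FFT"]] + toe_lag_pct)
  act_pct <- stats::approx(act_x, act_y, xout = proj_t,
                           ties = "ordered")$y
  deact_x <- c(lo, patch, q1, q2, toe_patch, hi)
  deact_y <- c(heel_off_onset_pct, heel_off_onset_pct,
               ev[["HOT"]], ev[["MOF"]], 100, 100)
  deact_pct <- stats::approx(deact_x, deact_y, xout = proj_t,
                             ties = "ordered")$y
  # Rollover clock: real stance time maps to model time through a strictly
  # increasing warp that runs at half speed inside a window around first
  # contact, every stance event and last contact. The whole pressure
  # field evolves on the warped clock, so the COP slows down near every
  # subphase boundary: frame-resolution event snapping then neither
  # misattributes large COP movements across a boundary nor biases the
  # path/duration ratio the way a fully frozen boundary would. The
  # windows are centered on the *realized* events of this rasterized
  # footfall (first/last activation or deactivation in the relevant
  # third), which the warp maps to themselves, so realized event times
  # are identical on both clocks.
  thirds <- axis$thirds
  need <- ceiling(0.78 * n)
  evs <- c(0, min(act_pct[thirds == 2]), sort(act_pct)[need],
           max(deact_pct[thirds == 1]), max(deact_pct[thirds == 2]), 100)
  evs <- sort(evs)
  w <- min(1.5, 0.45 * min(diff(evs)))
  if (w > 0.05) {
    s <- w / 2
    rknots <- c(0, w,
                as.vector(vapply(evs[2:5], function(e) c(e - w, e, e + w),
                                 numeric(3))),
                100 - w, 100)
    mknots <- c(0, s,
                as.vector(vapply(evs[2:5], function(e) c(e - s, e, e + s),
                                 numeric(3))),
                100 - s, 100)
  } else {
    rknots <- c(0, 100)  # degenerate event spacing: identity clock
    mknots <- c(0, 100)
  }
  model_of_real <- function(r) {
    stats::approx(rknots, mknots, xout = r, rule = 2, ties = "ordered")$y
  }
  real_of_model <- function(m) {
    stats::approx(mknots, rknots, xout = m, rule = 2, ties = "ordered")$y
  }
  # per-band base weights centered laterally: within each timing band the
  # unmodulated pressure centroid lies on the foot axis, so the planted
  # mediolateral COP excursion comes only from the slow sway modulation
  # and not from raster jaggedness of the outline
  band <- as.integer(round((proj - min(proj)) / cell_pitch))
  base_w <- rep(1, n)
  for (bd in unique(band)) {
    idx <- band == bd
    sv2 <- sum(vx[idx]^2)
    if (sv2 > 1e-9) {
      al <- -sum(vx[idx]) / sv2
      lim <- 0.8 / max(abs(vx[idx]))
      al <- max(min(al, lim), -lim)
      base_w[idx] <- 1 + al * vx[idx]
    }
  }
  t_on <- t0_ms + real_of_model(act_pct) / 100 * stance_ms
  t_off <- t0_ms + real_of_model(deact_pct) / 100 * stance_ms
  frame_ms <- 1000 / sampling_rate
  if (time_jitter_ms > 0) {
    t_on <- t_on + stats::rnorm(n, 0, time_jitter_ms)
    t_off <- t_off + stats::rnorm(n, 0, time_jitter_ms)
  }
  t_on <- pmax(t_on, 0)
  t_off <- pmax(t_off, t_on + 2 * frame_ms)
  cells$t_on_ms <- t_on
  cells$t_off_ms <- t_off

  # ground-truth events from the continuous times (detector rules)
  thirds <- axis$thirds
  need <- ceiling(0.78 * n)
  ev_true <- structure(list(
    FCT = min(t_on), MON = min(t_on[thirds == 2]),
    FFT = sort(t_on)[need], HOT = max(t_off[thirds == 1]),
    MOF = max(t_off[thirds == 2]), LCT = max(t_off),
    stance_ms = max(t_off) - min(t_on), valid = TRUE),
    class = "stance_events")
  ev_true$valid <- !is.unsorted(c(ev_true$FCT, ev_true$MON, ev_true$FFT,
                                  ev_true$HOT, ev_true$MOF, ev_true$LCT))

  # pressure field at arbitrary absolute times, on the warped clock;
  # returns a [time x cell] matrix, zero where a cell is inactive
  m_on <- model_of_real((t_on - t0_ms) / stance_ms * 100)
  m_off <- model_of_real((t_off - t0_ms) / stance_ms * 100)
  m_span <- pmax(m_off - m_on, 1e-6)
  press_at <- function(t_ms) {
    mt <- model_of_real((t_ms - t0_ms) / stance_ms * 100)
    nt <- length(t_ms)
    tau <- (matrix(mt, nt, n) - matrix(m_on, nt, n, byrow = TRUE)) /
      matrix(m_span, nt, n, byrow = TRUE)
    pm <- rollover_pressure(tau, matrix(vx / foot_width, nt, n,
                                        byrow = TRUE),
                            mt / 100, ml_sway)
    pm <- sweep(pm, 2, base_w, `*`)
    pm * (outer(t_ms, t_on, ">=") & outer(t_ms, t_off, "<="))
  }

  # frame-sampled recording
  frs <- ceiling(min(t_on) / frame_ms):floor(max(t_off) / frame_ms)
  Pm <- press_at(frs * frame_ms)
  active <- outer(frs * frame_ms, t_on, ">=") &
    outer(frs * frame_ms, t_off, "<=")
  hit <- which(active, arr.ind = TRUE)
  frames <- data.frame(frame = frs[hit[, 1]], row = cells$row[hit[, 2]],
                       col = cells$col[hit[, 2]],
                       pressure = Pm[hit])
  if (dropout_rate > 0) {
    frames <- frames[stats::runif(nrow(frames)) >= dropout_rate, ,
                     drop = FALSE]
  }
  frames <- frames[order(frames$frame, frames$row, frames$col), ]
  rownames(frames) <- NULL

  truth <- list(side = side, theta_c = theta,
                heel_point = c(a = heel_a, b = heel_b),
                toe_point = c(a = heel_a + foot_length * dvec[1],
                              b = heel_b + foot_length * dvec[2]),
                foot_length = foot_length, foot_width = foot_width,
                events = ev_true, axis = axis)
  truth <- c(truth, truth_parameters(press_at, vx, proj, axis, ev_true,
                                     side))
  list(cells = cells, frames = frames, truth = truth)
}

# Along-axis projection offset so that proj = y + offset equals the raw
# projection of cell centers onto the axis direction (origin-free extent).
axis_proj_offset <- function(axis) {
  axis$H[["a"]] * sin(axis$theta_c) + axis$H[["b"]] * cos(axis$theta_c)
}

# Dense continuous-time COP trajectory and the true parameter row.
truth_parameters <- function(press_at, vx, proj, axis, ev_true, side) {
  tg <- seq(ev_true$FCT, ev_true$LCT, by = 1)
  pm <- press_at(tg)
  tot <- rowSums(pm)
  keep <- tot > 0
  mirror <- if (identical(side, "left")) -1 else 1
  x <- mirror * as.vector(pm %*% vx)[keep] / tot[keep]
  y <- as.vector(pm %*% (proj - axis_proj_offset(axis)))[keep] / tot[keep]
  traj <- data.frame(time_ms = tg[keep], a = NA_real_, b = NA_real_,
                     x = x, y = y)
  traj <- structure(traj, side = side, index = NA_integer_,
                    foot_length = axis$foot_length,
                    foot_width = axis$foot_width,
                    class = c("cop_trajectory", "data.frame"))
  if (!isTRUE(ev_true$valid)) return(list(traj = traj, params = NULL))
  evn <- normalize_events(ev_true)
  list(traj = traj, params = footfall_parameters(traj, evn))
}

#' Generate a synthetic walkway recording with ground truth
#'
#' Plants `n_steps` alternating left/right rollover footfalls with forward
#' progression along the mat's long axis, at the pace, anthropometrics and
#' event timing drawn from the config's cohort distributions (one subject
#' per recording). Deterministic for a given seed.
#'
#' @param cfg a [synth_config()].
#' @param seed overrides `cfg$seed` when given.
#' @param subject_traits optional pre-drawn subject traits (from
#'   [draw_subject()]), for multi-pass designs where the same subject walks
#'   several recordings.
#' @param start_side side of the first footfall, default `"right"`.
#' @return List `recording` ([mat_recording()]) and `truth`: per-footfall
#'   ground-truth list plus the drawn `subject_traits`.
#' @export
generate_recording <- function(cfg = synth_config(), seed = cfg$seed,
                               subject_traits = NULL,
                               start_side = "right") {
  if (!is.null(seed)) set.seed(seed)
  tr <- subject_traits %||% draw_subject(cfg)
  step_period <- 60000 / tr$cadence                     # ms per step
  step_len <- tr$speed * 10 * step_period / 1000        # mm per step
  mat_len <- cfg$grid_rows * cfg$cell_pitch
  start_b <- tr$foot_width  # keep the heel clear of the mat edge
  n_steps <- cfg$n_steps
  if (isTRUE(cfg$fit_steps)) {
    # long-striding subjects fit fewer footfalls on one walkway pass
    capacity <- 1 + floor((mat_len - start_b - tr$foot_length -
                             tr$foot_width) / step_len)
    n_steps <- max(2L, min(n_steps, capacity))
  }
  need <- start_b + (n_steps - 1) * step_len + tr$foot_length +
    tr$foot_width
  if (need > mat_len)
    stop(sprintf("mat too small for %d steps (need %.0f mm, have %.0f mm)",
                 n_steps, need, mat_len))
  mid_a <- cfg$grid_cols * cfg$cell_pitch / 2
  sides <- rep(c(start_side, setdiff(c("left", "right"), start_side)),
               length.out = n_steps)
  ffs <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    sgn <- if (sides[i] == "right") 1 else -1
    jit <- if (cfg$placement_jitter_mm > 0)
      stats::rnorm(2, 0, cfg$placement_jitter_mm) else c(0, 0)
    evf <- clamp_event_pct(tr$event_mean +
                             stats::rnorm(4, 0, cfg$event_pct[, "within_sd"]))
    stance_i <- max(200, tr$stance_mean +
                      stats::rnorm(1, 0, cfg$stance[3]))
    theta_i <- sgn * tr$toe_out +
      stats::rnorm(1, 0, cfg$toe_out_deg[3])
    ffs[[i]] <- generate_footfall(
      heel_a = mid_a + sgn * cfg$step_width_mm / 2 + jit[1],
      heel_b = start_b + (i - 1) * step_len + jit[2],
      theta_deg = theta_i, side = sides[i],
      foot_length = tr$foot_length, foot_width = tr$foot_width,
      stance_ms = stance_i,
      # contact times are asynchronous with the sampling clock
      t0_ms = (i - 1) * step_period +
        stats::runif(1, 0, 1000 / cfg$sampling_rate),
      event_pct = evf, heel_off_onset_pct = cfg$heel_off_onset_pct,
      ml_sway = cfg$ml_sway, time_jitter_ms = cfg$time_jitter_ms,
      dropout_rate = cfg$dropout_rate, cell_pitch = cfg$cell_pitch,
      sampling_rate = cfg$sampling_rate, grid_rows = cfg$grid_rows,
      grid_cols = cfg$grid_cols)
  }
  cells <- do.call(rbind, lapply(ffs, `[[`, "frames"))
  rec <- mat_recording(cells, sampling_rate = cfg$sampling_rate,
                       cell_pitch = cfg$cell_pitch,
                       grid_rows = cfg$grid_rows,
                       grid_cols = cfg$grid_cols)
  list(recording = rec,
       truth = list(footfalls = lapply(ffs, `[[`, "truth"),
                    sides = sides, subject_traits = tr))
}

#' Draw subject-level traits from the cohort distributions
#'
#' @param cfg a [synth_config()].
#' @return List with `foot_length`, `foot_width`, `speed`, `cadence`,
#'   `stance_mean`, `toe_out` and `event_mean` (the subject's mean event
#'   percentages).
#' @export
draw_subject <- function(cfg) {
  list(
    foot_length = max(160, stats::rnorm(1, cfg$foot_length[1],
                                        cfg$foot_length[2])),
    foot_width = max(70, stats::rnorm(1, cfg$foot_width[1],
                                      cfg$foot_width[2])),
    speed = max(60, stats::rnorm(1, cfg$speed[1], cfg$speed[2])),
    cadence = max(70, stats::rnorm(1, cfg$cadence[1], cfg$cadence[2])),
    stance_mean = max(250, stats::rnorm(1, cfg$stance[1], cfg$stance[2])),
    toe_out = stats::rnorm(1, cfg$toe_out_deg[1], cfg$toe_out_deg[2]),
    event_mean = clamp_event_pct(
      cfg$event_pct[, "mean"] +
        stats::rnorm(4, 0, cfg$event_pct[, "between_sd"]))
  )
}

# Enforce the ordering 0 < MON < FFT < HOT < MOF < 100 with margins wide
# enough that one cell pitch of contact-wave slack cannot reorder the
# realized events.
clamp_event_pct <- function(e) {
  e <- stats::setNames(as.numeric(e), c("MON", "FFT", "HOT", "MOF"))
  e[["MON"]] <- min(max(e[["MON"]], 2), 25)
  e[["FFT"]] <- min(max(e[["FFT"]], e[["MON"]] + 4), 65)
  e[["HOT"]] <- min(max(e[["HOT"]], e[["FFT"]] + 10), 85)
  e[["MOF"]] <- min(max(e[["MOF"]], e[["HOT"]] + 5), 96)
  e
}

#' Generate a synthetic cohort of walkway recordings
#'
#' Draws `cfg$n_subjects` subjects and, for each, enough walkway passes for
#' at least `cfg$footfalls_per_side` footfalls per side (pass starting side
#' alternates so both feet accumulate evenly).
#'
#' @param cfg a [synth_config()].
#' @param seed overrides `cfg$seed`.
#' @param condition label stored alongside each recording, default the
#'   config's pace.
#' @return List with `recordings` (flat list), `subject` / `condition`
#'   vectors aligned with it, and `truth` (per recording).
#' @export
generate_cohort <- function(cfg = synth_config(), seed = cfg$seed,
                            condition = cfg$pace) {
  if (!is.null(seed)) set.seed(seed)
  per_side_per_pass <- floor(cfg$n_steps / 2)
  n_pass <- ceiling(cfg$footfalls_per_side / per_side_per_pass)
  recs <- list(); subj <- character(); truths <- list()
  for (s in seq_len(cfg$n_subjects)) {
    tr <- draw_subject(cfg)
    for (p in seq_len(n_pass)) {
      g <- generate_recording(cfg, seed = NULL, subject_traits = tr,
                              start_side = if (p %% 2) "right" else "left")
      recs[[length(recs) + 1]] <- g$recording
      truths[[length(truths) + 1]] <- g$truth
      subj <- c(subj, sprintf("S%02d", s))
    }
  }
  list(recordings = recs, subject = subj,
       condition = rep(condition, length(recs)), truth = truths)
}

#' Generate a subject x footfall measurement matrix with known reliability
#'
#' Values follow the two-variance-component model
#' `value[i, j] = mu + b_i + e_ij` with `b ~ N(0, sigma_between^2)` and
#' `e ~ N(0, sigma_within^2)`, so the true single-measurement ICC is
#' `sigma_between^2 / (sigma_between^2 + sigma_within^2)`.
#'
#' @param n subjects (rows); `k` footfalls (columns).
#' @param mu grand mean.
#' @param sigma_between,sigma_within component SDs (>= 0).
#' @param seed optional seed.
#' @return List `M` (n x k matrix) and `true_icc`.
#' @export
generate_parameter_matrix <- function(n, k, mu = 0, sigma_between = 1,
                                      sigma_within = 1, seed = NULL) {
  stopifnot(sigma_between >= 0, sigma_within >= 0)
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n, 0, sigma_between)
  e <- matrix(stats::rnorm(n * k, 0, sigma_within), n, k)
  M <- mu + b + e
  denom <- sigma_between^2 + sigma_within^2
  list(M = M, true_icc = if (denom > 0) sigma_between^2 / denom else NA_real_)
}
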