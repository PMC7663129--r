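#' Cluster active cells into footfalls
#'
#' Groups the recording's active cells into foot contacts. Each cell's
#' activity is first split into temporal runs (a cell may be re-used by a
#' later step); two runs belong to the same footfall when their cells are
#' 8-connected in space and their active intervals overlap or are separated
#' by at most `max_gap` frames. Components with fewer than `min_cells`
#' distinct cells are discarded as noise.
#'
#' @param rec a [mat_recording()].
#' @param min_cells minimum number of distinct cells per footfall.
#' @param max_gap maximum tolerated gap, in frames, both within a single
#'   cell's activity and between temporally adjacent runs.
#' @return A list of `footfall` objects ordered by first contact time. Each
#'   has `cells` (row, col, first-activation / last-deactivation frames and
#'   ms), `frames` (the per-frame cell samples with pressure), `index`,
#'   `side` (initially `"unknown"`), the time span, and the recording's
#'   sampling rate / pitch / walking axis.
#' @seealso [assign_sides()], [estimate_axis()]
#' @export
detect_footfalls <- function(rec, min_cells = 5, max_gap = 2) {
  validate_recording(rec)
  cl <- rec$cells
  if (!nrow(cl)) return(list())

  cell_id <- cl$row * rec$grid_cols + cl$col
  ord <- order(cell_id, cl$frame)
  fr <- cl$frame[ord]
  cid <- cell_id[ord]
  # split each cell's frame sequence into runs with gaps <= max_gap
  new_run <- c(TRUE, cid[-1] != cid[-length(cid)] |
                 diff(fr) > max_gap + 1)
  run_id <- cumsum(new_run)
  runs <- data.frame(
    cell = cid[new_run],
    f_on = fr[new_run],
    f_off = tapply(fr, run_id, max)[as.character(seq_len(sum(new_run)))]
  )
  runs$f_off <- as.integer(runs$f_off)
  runs$row <- runs$cell %/% rec$grid_cols
  runs$col <- runs$cell %% rec$grid_cols
  comp <- cluster_runs(runs, max_gap)

  ms <- 1000 / rec$sampling_rate
  row_run <- run_id  # run id per ordered cell sample
  out <- list()
  for (cp in sort(unique(comp))) {
    rn <- which(comp == cp)
    if (length(unique(runs$cell[rn])) < min_cells) next
    sel <- ord[row_run %in% rn]
    frames <- cl[sel, , drop = FALSE]
    frames <- frames[order(frames$frame, frames$row, frames$col), ]
    rownames(frames) <- NULL
    sub <- runs[rn, ]
    cells <- data.frame(
      row = as.integer(tapply(sub$row, sub$cell, `[`, 1)),
      col = as.integer(tapply(sub$col, sub$cell, `[`, 1)),
      f_on = as.integer(tapply(sub$f_on, sub$cell, min)),
      f_off = as.integer(tapply(sub$f_off, sub$cell, max))
    )
    cells <- cells[order(cells$f_on, cells$row, cells$col), ]
    rownames(cells) <- NULL
    cells$t_on_ms <- cells$f_on * ms
    cells$t_off_ms <- cells$f_off * ms
    out[[length(out) + 1]] <- structure(
      list(cells = cells, frames = frames, index = NA_integer_,
           side = "unknown",
           t_first_ms = min(cells$t_on_ms), t_last_ms = max(cells$t_off_ms),
           sampling_rate = rec$sampling_rate, cell_pitch = rec$cell_pitch,
           walking_axis = rec$walking_axis),
      class = "footfall")
  }
  out <- out[order(vapply(out, function(f) f$t_first_ms, 0))]
  for (i in seq_along(out)) out[[i]]$index <- i
  out
}

# Union of runs that are 8-adjacent in space and contiguous in time.
cluster_runs <- function(runs, max_gap) {
  n <- nrow(runs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # candidate pairs: restrict to spatial neighbours via sorted row blocks
  ordr <- order(runs$row, runs$col)
  rr <- runs$row[ordr]; cc <- runs$col[ordr]
  on <- runs$f_on[ordr]; off <- runs$f_off[ordr]
  for (i in seq_len(n)) {
    # scan forward while row within +1 (rows sorted)
    j <- i + 1
    while (j <= n && rr[j] <= rr[i] + 1) {
      if (abs(cc[j] - cc[i]) <= 1 &&
          on[j] <= off[i] + max_gap && on[i] <= off[j] + max_gap) {
        ri <- find(ordr[i]); rj <- find(ordr[j])
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' @export
print.footfall <- function(x, ...) {
  cat(sprintf(
    "<footfall %s> %d cells, side=%s, %.1f-%.1f ms\n",
    ifelse(is.na(x$index), "?", x$index), nrow(x$cells), x$side,
    x$t_first_ms, x$t_last_ms))
  invisible(x)
}

#' Assign left/right side labels to an ordered footfall sequence
#'
#' During straight walking, alternate steps fall on alternate sides of the
#' line of progression. The running midline is the least-squares line of the
#' footfall centroids along the walking axis; the sign of each centroid's
#' lateral offset from that line determines its side. With the default
#' walking direction (increasing `b`), a centroid at smaller `a` lies on the
#' walker's left. Sequences whose offsets do not alternate are flagged
#' `"unknown"` rather than guessed, as is a singleton footfall.
#'
#' @param footfalls list of `footfall` objects in first-contact order.
#' @return The list with `side` set on each footfall.
#' @export
assign_sides <- function(footfalls) {
  n <- length(footfalls)
  if (n == 0) return(footfalls)
  if (n == 1) {
    footfalls[[1]]$side <- "unknown"
    return(footfalls)
  }
  pitch <- footfalls[[1]]$cell_pitch
  cent <- t(vapply(footfalls, function(f) {
    colMeans(cell_center(f$cells$row, f$cells$col, pitch))
  }, c(a = 0, b = 0)))
  dirn <- if (footfalls[[1]]$walking_axis == "+b") 1 else -1
  # lateral offset from the least-squares midline a ~ b
  if (length(unique(cent[, "b"])) > 1) {
    fit <- stats::lm.fit(cbind(1, cent[, "b"]), cent[, "a"])
    offset <- fit$residuals
  } else {
    offset <- cent[, "a"] - mean(cent[, "a"])
  }
  # walking toward +b: left side lies at smaller a
  side <- ifelse(dirn * offset < 0, "left", "right")
  side[offset == 0] <- "unknown"
  for (i in 2:n) {
    if (side[i] != "unknown" && side[i] == side[i - 1]) side[i] <- "unknown"
  }
  for (i in seq_len(n)) footfalls[[i]]$side <- side[i]
  footfalls
}
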