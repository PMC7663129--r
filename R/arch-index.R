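#' Remove the toes from a static footprint
#'
#' The arch index is defined on the footprint with the toes excluded. When
#' the footprint carries an explicit toe mask (`is_toe`), exactly those
#' cells are removed. Otherwise a geometric heuristic is used: connected
#' components (8-connectivity) lying entirely distal to the most distal
#' empty cross-section row of the main (largest) component are taken to be
#' detached toe prints and removed. If the heuristic would remove more than
#' 40\% of the footprint area it errors and demands an explicit mask.
#'
#' @param fp a [footprint_grid()].
#' @param distal which end of the row axis holds the toes: `"high_row"`
#'   (default) or `"low_row"`.
#' @return A toe-excluded [footprint_grid()].
#' @export
exclude_toes <- function(fp, distal = c("high_row", "low_row")) {
  distal <- match.arg(distal)
  cells <- fp$cells
  if (any(cells$is_toe)) {
    keep <- cells[!cells$is_toe, , drop = FALSE]
    if (!nrow(keep)) stop("toe mask covers the whole footprint")
    return(footprint_grid(keep, fp$cell_pitch))
  }
  comp <- grid_components(cells$row, cells$col)
  main <- which.max(tabulate(comp))
  occ_rows <- sort(unique(cells$row))
  all_rows <- seq(min(occ_rows), max(occ_rows))
  gap_rows <- setdiff(all_rows, occ_rows)
  if (distal == "low_row") {
    cells$row <- -cells$row
    gap_rows <- -gap_rows
  }
  main_max <- max(cells$row[comp == main])
  gap_rows <- gap_rows[gap_rows > main_max]
  if (!length(gap_rows)) {
    if (distal == "low_row") cells$row <- -cells$row
    return(footprint_grid(cells, fp$cell_pitch))
  }
  cut <- min(gap_rows)
  drop_comp <- unique(comp[cells$row > cut])
  drop <- comp %in% setdiff(drop_comp, main)
  if (sum(drop) > 0.4 * nrow(cells))
    stop("toe heuristic would remove > 40% of the footprint; ",
         "provide an explicit is_toe mask")
  keep <- cells[!drop, , drop = FALSE]
  if (distal == "low_row") keep$row <- -keep$row
  footprint_grid(keep, fp$cell_pitch)
}

# 8-connected components over a sparse cell set; returns component labels.
grid_components <- function(row, col) {
  n <- length(row)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ordr <- order(row, col)
  rr <- row[ordr]; cc <- col[ordr]
  for (i in seq_len(n)) {
    j <- i + 1
    while (j <= n && rr[j] <= rr[i] + 1) {
      if (abs(cc[j] - cc[i]) <= 1) {
        ri <- find(ordr[i]); rj <- find(ordr[j])
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Compute the arch index of a toe-excluded footprint
#'
#' The footprint's extent along the foot axis is divided into three
#' equal-length intervals; `a`, `b`, `c` are the contact areas of the
#' distal, middle and proximal thirds and the arch index is
#' `AI = b / (a + b + c)`. Areas are computed exactly: each occupied cell
#' spans one pitch along the axis and its area is apportioned between
#' intervals by fractional overlap, so a uniform rectangle yields exactly
#' 1/3 regardless of discretization.
#'
#' @param fp a toe-excluded [footprint_grid()].
#' @param axis grid axis running along the foot: `"rows"` (default) or
#'   `"cols"`.
#' @param distal which end of that axis is the forefoot: `"high"` (default)
#'   or `"low"`.
#' @return Object of class `arch_index`: list with areas `a`, `b`, `c`
#'   (cell-count units), `ai`, and `category` (`NA` until
#'   [classify_arch()] is applied).
#' @export
compute_arch_index <- function(fp, axis = c("rows", "cols"),
                               distal = c("high", "low")) {
  axis <- match.arg(axis)
  distal <- match.arg(distal)
  cells <- fp$cells
  if (!nrow(cells)) stop("empty footprint")
  pos <- if (axis == "rows") cells$row else cells$col
  if (distal == "low") pos <- -pos - 1  # cell spans [-pos-1, -pos)
  lo <- min(pos)
  len <- max(pos) + 1 - lo
  b1 <- lo + len / 3
  b2 <- lo + 2 * len / 3
  overlap <- function(s, e) pmax(0, pmin(pos + 1, e) - pmax(pos, s))
  c_area <- sum(overlap(lo, b1))        # proximal third
  b_area <- sum(overlap(b1, b2))        # middle third
  a_area <- sum(overlap(b2, lo + len))  # distal third
  structure(list(a = a_area, b = b_area, c = c_area,
                 ai = b_area / (a_area + b_area + c_area),
                 category = NA_character_),
            class = "arch_index")
}

#' @export
print.arch_index <- function(x, ...) {
  cat(sprintf("<arch_index> AI = %.4f (a=%.1f, b=%.1f, c=%.1f)%s\n",
              x$ai, x$a, x$b, x$c,
              if (is.na(x$category)) "" else paste0(", ", x$category, " arch")))
  invisible(x)
}

#' Classify the medial longitudinal arch from the arch index
#'
#' A small middle-third contact area signals a high arch, a large one a
#' flat (low) arch: `AI < thresholds[1]` is `"high"`, `AI >
#' thresholds[2]` is `"low"`, anything between is `"normal"`. The default
#' cut-offs 0.21 / 0.26 follow the conventional arch-index bands; they are
#' exposed because classification conventions differ between clinics.
#'
#' @param ai arch index in \[0, 1\], or an `arch_index` object.
#' @param thresholds increasing length-2 numeric `(low_cut, high_cut)`.
#' @return The category string, or the `arch_index` object with its
#'   `category` filled in.
#' @export
classify_arch <- function(ai, thresholds = c(0.21, 0.26)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("thresholds must be increasing (low_cut, high_cut)")
  obj <- NULL
  if (inherits(ai, "arch_index")) {
    obj <- ai
    ai <- ai$ai
  }
  if (is.na(ai) || ai < 0 || ai > 1) stop("arch index must be in [0, 1]")
  cat <- if (ai < thresholds[1]) "high"
         else if (ai > thresholds[2]) "low"
         else "normal"
  if (is.null(obj)) return(cat)
  obj$category <- cat
  obj
}
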