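#' Estimate the foot axis, heel/toe centers and thirds of a footfall
#'
#' The foot axis is the line `l` from the heel center `H` to the toe center
#' `T`. `H` and `T` are the pivot points of the proximal and distal
#' one-third of the footfall, taken as the area centroids of those cell
#' sets. Because the thirds themselves require an axis, the estimate is
#' bootstrapped: a provisional axis (principal axis of the cell centers,
#' oriented toward the walking direction) defines provisional thirds, which
#' give provisional `H`/`T`; one refinement pass then recomputes the thirds
#' along the line `H`-`T` and the centroids once more. Thirds divide the
#' extent of the cell-center projections into three equal intervals; a
#' center exactly on a boundary is assigned to the more proximal interval.
#'
#' The rotation angle `theta_c` between the mat's vertical axis and `l` is
#' `atan2(c - e, d - f)` for `T = (c, d)`, `H = (e, f)`; with this sign
#' convention [transform_point()] maps `T` onto the positive y-axis. The
#' inclination `theta_o = atan2(d - f, c - e)` is kept for reference. Foot
#' length and width are the cell-center extents along and perpendicular to
#' `l` plus one cell pitch, since centers alone underestimate the physical
#' outline by half a cell at each end.
#'
#' @param ff a `footfall` from [detect_footfalls()], or any list with a
#'   `cells` data.frame holding `row`/`col`.
#' @param cell_pitch cell spacing in mm; defaults to the footfall's.
#' @return An object of class `foot_axis`: list with `H`, `T` (named mm
#'   vectors `a`,`b`), `theta_c`, `theta_o` (radians), `foot_length`,
#'   `foot_width` (mm), `thirds` (integer vector, 1 = proximal, 2 = middle,
#'   3 = distal, aligned with `ff$cells`), and `cell_pitch`.
#' @export
estimate_axis <- function(ff, cell_pitch = NULL) {
  cells <- ff$cells
  pitch <- cell_pitch %||% ff$cell_pitch
  if (is.null(pitch)) stop("cell_pitch not available")
  if (nrow(cells) < 3)
    stop("degenerate footfall ", ff$index %||% "?",
         ": fewer than 3 cells")
  P <- cell_center(cells$row, cells$col, pitch)
  wdir <- if ((ff$walking_axis %||% "+b") == "+b") c(0, 1) else c(0, -1)

  # provisional axis: principal axis of the cell centers
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v * wdir) < 0) v <- -v
  if (ev$values[1] <= .Machine$double.eps * max(1, ev$values[2]))
    stop("degenerate footfall ", ff$index %||% "?", ": no spatial extent")

  thirds <- split_thirds(P %*% v)
  if (!any(thirds == 1) || !any(thirds == 3))
    stop("degenerate footfall ", ff$index %||% "?",
         ": empty proximal or distal third")
  H <- colMeans(P[thirds == 1, , drop = FALSE])
  T <- colMeans(P[thirds == 3, , drop = FALSE])

  # one refinement pass along the line l from H to T
  l <- T - H
  if (sqrt(sum(l^2)) <= .Machine$double.eps)
    stop("degenerate footfall ", ff$index %||% "?", ": H equals T")
  l <- l / sqrt(sum(l^2))
  thirds <- split_thirds(P %*% l)
  if (!any(thirds == 1) || !any(thirds == 3))
    stop("degenerate footfall ", ff$index %||% "?",
         ": empty proximal or distal third")
  H <- colMeans(P[thirds == 1, , drop = FALSE])
  T <- colMeans(P[thirds == 3, , drop = FALSE])
  d <- T - H
  hyp <- sqrt(sum(d^2))
  if (hyp <= .Machine$double.eps)
    stop("degenerate footfall ", ff$index %||% "?", ": H equals T")

  theta_c <- atan2(d[["a"]], d[["b"]])
  theta_o <- atan2(d[["b"]], d[["a"]])
  ldir <- d / hyp
  ndir <- c(ldir[2], -ldir[1])
  along <- P %*% ldir
  across <- P %*% ndir
  structure(
    list(H = c(a = H[["a"]], b = H[["b"]]),
         T = c(a = T[["a"]], b = T[["b"]]),
         theta_c = theta_c, theta_o = theta_o,
         foot_length = diff(range(along)) + pitch,
         foot_width = diff(range(across)) + pitch,
         thirds = thirds, cell_pitch = pitch),
    class = "foot_axis")
}

# Partition scalar projections into extent thirds; boundary ties go to the
# more proximal interval.
split_thirds <- function(proj) {
  lo <- min(proj); hi <- max(proj)
  len <- hi - lo
  eps <- 1e-9 * max(1, abs(hi), abs(lo))
  q1 <- lo + len / 3
  q2 <- lo + 2 * len / 3
  ifelse(proj <= q1 + eps, 1L, ifelse(proj <= q2 + eps, 2L, 3L))
}

#' @export
print.foot_axis <- function(x, ...) {
  cat(sprintf(
    "<foot_axis> H=(%.1f, %.1f) T=(%.1f, %.1f) mm, theta_c=%.1f deg, %.0f x %.0f mm\n",
    x$H[1], x$H[2], x$T[1], x$T[2], x$theta_c * 180 / pi,
    x$foot_length, x$foot_width))
  invisible(x)
}

#' Convert mat-frame coordinates into the foot frame
#'
#' Applies the per-footfall rigid transform: translation of the heel center
#' `H` to the origin followed by rotation through `theta_c`, so that the
#' foot axis `l` becomes the positive y-axis (anteroposterior, heel to toe).
#' For left feet the x-coordinate is negated afterwards so that positive x
#' always points from the medial to the lateral side of the foot, making
#' left and right trajectories directly comparable.
#'
#' @param p_raw numeric length-2 vector `(a, b)` or an n x 2 matrix of
#'   mat-frame points, mm.
#' @param axis a [estimate_axis()] result (anything with `H` and `theta_c`).
#' @param side `"right"` (default), `"left"`, or `"unknown"` (treated as
#'   right, i.e. no mirroring).
#' @return Transformed coordinates in mm, same shape as the input, columns
#'   `x` (mediolateral) and `y` (anteroposterior).
#' @examples
#' ax <- list(H = c(a = 10, b = 20), theta_c = 0)
#' transform_point(c(13, 50), ax)   # (3, 30)
#' @export
transform_point <- function(p_raw, axis, side = "right") {
  p <- if (is.matrix(p_raw)) p_raw else matrix(p_raw, ncol = 2)
  th <- axis$theta_c
  da <- p[, 1] - axis$H[[1]]
  db <- p[, 2] - axis$H[[2]]
  x <- cos(th) * da - sin(th) * db
  y <- sin(th) * da + cos(th) * db
  if (identical(side, "left")) x <- -x
  out <- cbind(x = x, y = y)
  if (!is.matrix(p_raw)) out[1, ] else out
}
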