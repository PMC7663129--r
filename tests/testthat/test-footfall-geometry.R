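test_that("axis of a vertical block: heel below toe, sizes include one pitch", {
  ff <- make_footfall(block_cells(), cell_pitch = 10)
  ax <- estimate_axis(ff)
  expect_equal(ax$theta_c, 0, tolerance = 1e-12)
  expect_lt(ax$H[["b"]], ax$T[["b"]])
  expect_equal(ax$foot_length, 90)
  expect_equal(ax$foot_width, 30)
  expect_setequal(unique(ax$thirds), 1:3)
})

test_that("rotating a footfall rotates the estimated axis with it", {
  cells <- block_cells()
  P <- cell_center(cells$row, cells$col, 10)
  ctr <- colMeans(P)
  for (ang in c(45, -30) * pi / 180) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    Q <- sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, `+`)
    # re-rasterize the rotated centers onto a fine grid
    rot <- data.frame(row = round(Q[, 2] / 1) , col = round(Q[, 1] / 1))
    rot <- rot[!duplicated(rot), ]
    ax <- estimate_axis(make_footfall(rot, cell_pitch = 1))
    # Eq.-style invariant: T maps to (0, |HT|)
    tt <- transform_point(ax$T, ax)
    hyp <- sqrt(sum((ax$T - ax$H)^2))
    expect_equal(unname(tt), c(0, hyp), tolerance = 1e-9)
    expect_equal(abs(ax$theta_c), abs(ang), tolerance = 0.15)
  }
})

test_that("mirroring a footfall flips the sign of theta_c only", {
  co <- synth_footfall(seed = 3, theta_deg = 6)
  cells <- co$ff$cells
  mirr <- cells
  mirr$col <- 47 - mirr$col
  ax1 <- estimate_axis(make_footfall(cells))
  ax2 <- estimate_axis(make_footfall(mirr))
  expect_equal(ax2$theta_c, -ax1$theta_c, tolerance = 1e-9)
  expect_equal(ax2$foot_length, ax1$foot_length, tolerance = 1e-9)
  expect_equal(ax2$foot_width, ax1$foot_width, tolerance = 1e-9)
})

test_that("degenerate footfalls are rejected by name", {
  tiny <- make_footfall(data.frame(row = 0:1, col = 0))
  expect_error(estimate_axis(tiny), "degenerate")
})

test_that("transform_point matches the worked rigid-motion examples", {
  ax45 <- list(H = c(a = 0, b = 0), theta_c = atan2(100, 100))
  expect_equal(unname(transform_point(c(100, 100), ax45)),
               c(0, sqrt(2) * 100), tolerance = 1e-9)
  ax0 <- list(H = c(a = 10, b = 20), theta_c = 0)
  expect_equal(unname(transform_point(c(13, 50), ax0)), c(3, 30))
  expect_equal(unname(transform_point(c(10, 20), ax0)), c(0, 0))
  # left feet mirror the mediolateral axis
  expect_equal(unname(transform_point(c(13, 50), ax0, side = "left")),
               c(-3, 30))
})

test_that("the foot-frame transform is an isometry before mirroring", {
  set.seed(7)
  for (i in 1:20) {
    ax <- list(H = c(a = runif(1, -50, 50), b = runif(1, -50, 50)),
               theta_c = runif(1, -pi, pi))
    P <- matrix(runif(20, -100, 100), ncol = 2)
    Q <- transform_point(P, ax)
    expect_equal(as.vector(dist(Q)), as.vector(dist(P)), tolerance = 1e-9)
  }
})

test_that("detected footfalls match spatial/temporal clustering rules", {
  # two footfalls separated in space and time
  ms <- 1000 / 240
  f1 <- expand.grid(row = 0:3, col = 0:2)
  f2 <- expand.grid(row = 30:33, col = 5:7)
  cells <- rbind(
    data.frame(frame = rep(0:10, each = nrow(f1)), f1[rep(1:nrow(f1), 11), ],
               pressure = 1),
    data.frame(frame = rep(40:50, each = nrow(f2)), f2[rep(1:nrow(f2), 11), ],
               pressure = 1))
  rec <- mat_recording(cells, grid_rows = 64, grid_cols = 16)
  ffs <- detect_footfalls(rec)
  expect_length(ffs, 2)
  expect_equal(ffs[[1]]$t_first_ms, 0)
  expect_equal(ffs[[2]]$t_first_ms, 40 * ms)
  expect_equal(nrow(ffs[[1]]$cells), nrow(f1))
  # below min_cells the cluster is dropped
  ffs2 <- detect_footfalls(rec, min_cells = 13)
  expect_length(ffs2, 0)
})

test_that("a single cluster re-used later in time splits at max_gap", {
  f <- expand.grid(row = 0:3, col = 0:2)
  cells <- rbind(
    data.frame(frame = rep(0:5, each = nrow(f)), f[rep(1:nrow(f), 6), ],
               pressure = 1),
    data.frame(frame = rep(20:25, each = nrow(f)), f[rep(1:nrow(f), 6), ],
               pressure = 1))
  rec <- mat_recording(cells, grid_rows = 16, grid_cols = 8)
  expect_length(detect_footfalls(rec, max_gap = 2), 2)
  expect_length(detect_footfalls(rec, max_gap = 20), 1)
})

test_that("side assignment alternates with centroid offsets", {
  mk <- function(rows, cols) {
    f <- expand.grid(row = rows, col = cols)
    data.frame(frame = 0, f, pressure = 1)
  }
  # right of midline first (walking +b, larger a = right)
  cells <- rbind(
    transform(mk(0:3, 10:12), frame = 0),
    transform(mk(20:23, 2:4), frame = 30),
    transform(mk(40:43, 10:12), frame = 60))
  cells <- cells[order(cells$frame), ]
  rec <- mat_recording(cells, grid_rows = 64, grid_cols = 16)
  ffs <- assign_sides(detect_footfalls(rec))
  expect_equal(vapply(ffs, `[[`, "", "side"), c("right", "left", "right"))
  # singleton stays unknown
  rec1 <- mat_recording(mk(0:3, 10:12), grid_rows = 16, grid_cols = 16)
  expect_equal(assign_sides(detect_footfalls(rec1))[[1]]$side, "unknown")
})

test_that("non-alternating geometry is flagged unknown, not guessed", {
  mk <- function(rows, cols, fr) {
    data.frame(frame = fr, expand.grid(row = rows, col = cols), pressure = 1)
  }
  cells <- rbind(mk(0:3, 10:12, 0), mk(20:23, 10:12, 30),
                 mk(40:43, 10:12, 60), mk(60:63, 2:4, 90))
  rec <- mat_recording(cells[order(cells$frame), ],
                       grid_rows = 80, grid_cols = 16)
  sides <- vapply(assign_sides(detect_footfalls(rec)), `[[`, "", "side")
  expect_true("unknown" %in% sides)
})
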