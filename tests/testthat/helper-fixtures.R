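# Shared fixtures built in code.

# A footfall object assembled by hand (bypassing detect_footfalls).
make_footfall <- function(cells, sampling_rate = 240, cell_pitch = 12.7,
                          walking_axis = "+b", frames = NULL,
                          side = "unknown") {
  structure(
    list(cells = cells, frames = frames, index = 1L, side = side,
         t_first_ms = if (!is.null(cells$t_on_ms)) min(cells$t_on_ms) else 0,
         t_last_ms = if (!is.null(cells$t_off_ms)) max(cells$t_off_ms) else 0,
         sampling_rate = sampling_rate, cell_pitch = cell_pitch,
         walking_axis = walking_axis),
    class = "footfall")
}

# Vertical 3 x 9 block of cells (cols 0..2, rows 0..8).
block_cells <- function() {
  expand.grid(row = 0:8, col = 0:2)
}

# Six cells in a single column with the worked activation pattern:
# two cells per third, activations at frames (0,1 | 3,4 | 6,7),
# deactivations at frames (10,11 | 14,15 | 18,19), 240 Hz, pitch 10 mm.
worked_six_cell_footfall <- function() {
  ms <- 1000 / 240
  cells <- data.frame(
    row = c(0, 1, 4, 5, 8, 9), col = 0,
    f_on = c(0, 1, 3, 4, 6, 7), f_off = c(10, 11, 14, 15, 18, 19))
  cells$t_on_ms <- cells$f_on * ms
  cells$t_off_ms <- cells$f_off * ms
  make_footfall(cells, cell_pitch = 10)
}

# A synthetic footfall wrapped as a footfall object, with its ground truth.
synth_footfall <- function(seed = 1, side = "right", theta_deg = 4, ...) {
  set.seed(seed)
  gf <- generate_footfall(heel_a = 300, heel_b = 120, theta_deg = theta_deg,
                          side = side, foot_length = 240, foot_width = 100,
                          stance_ms = 614, t0_ms = 0, grid_rows = 488, ...)
  ff <- make_footfall(gf$cells, frames = gf$frames, side = side)
  list(ff = ff, truth = gf$truth)
}

# Random small mat recording for round-trip property tests.
random_recording <- function(n = 30, grid_rows = 20, grid_cols = 10) {
  cells <- data.frame(
    frame = sort(sample(0:15, n, replace = TRUE)),
    row = sample(0:(grid_rows - 1), n, replace = TRUE),
    col = sample(0:(grid_cols - 1), n, replace = TRUE),
    pressure = round(stats::runif(n, 0, 5), 6))
  cells <- cells[!duplicated(cells[c("frame", "row", "col")]), ]
  mat_recording(cells, sampling_rate = 240, cell_pitch = 12.7,
                grid_rows = grid_rows, grid_cols = grid_cols)
}

# Brute-force two-way ANOVA mean squares from explicit sums of squares.
anova_bruteforce <- function(M) {
  n <- nrow(M); k <- ncol(M)
  g <- mean(M)
  ssr <- k * sum((rowMeans(M) - g)^2)
  ssc <- n * sum((colMeans(M) - g)^2)
  sst <- sum((M - g)^2)
  sse <- sst - ssr - ssc
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)), SST = sst, SSR = ssr,
       SSC = ssc, SSE = sse)
}
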