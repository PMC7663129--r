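test_that("frame COP is the pressure-weighted centroid of cell centers", {
  expect_equal(cop_of_frame(data.frame(row = 0, col = 0, pressure = 2), 12.7),
               c(a = 6.35, b = 6.35))
  two <- data.frame(row = c(0, 0), col = c(0, 1), pressure = c(1, 1))
  expect_equal(cop_of_frame(two, 10)[["a"]], 10)  # midpoint of 5 and 15
  wt <- data.frame(row = c(0, 0), col = c(0, 1), pressure = c(1, 3))
  expect_equal(cop_of_frame(wt, 10)[["a"]], 12.5)  # 5*0.25 + 15*0.75
  expect_null(cop_of_frame(data.frame(row = 0, col = 0, pressure = 0), 10))
})

make_traj <- function(time_ms, x, y, foot_length = 250, foot_width = 100) {
  structure(data.frame(time_ms = time_ms, a = x, b = y, x = x, y = y),
            side = "right", index = 1L, foot_length = foot_length,
            foot_width = foot_width,
            class = c("cop_trajectory", "data.frame"))
}

test_that("displacement ranges and mean locations follow their definitions", {
  tr <- make_traj(c(0, 10, 20), x = c(0, 3, 1), y = c(0, 50, 40))
  expect_equal(displacement_range(tr, c(0, 20), "ML"), 3)
  expect_equal(displacement_range(tr, c(0, 0), "ML"), 0)   # single sample
  expect_true(is.na(displacement_range(tr, c(30, 40), "ML")))
  expect_equal(mean_location(tr, c(0, 20), "ML"), 100 * (4 / 3) / 100)
  # negative anteroposterior mean: COP behind the heel center
  tr2 <- make_traj(c(0, 10), x = c(0, 0), y = c(-18.6, -18.6))
  expect_equal(round(mean_location(tr2, c(0, 10), "AP"), 2), -7.44)
  expect_equal(mean_location(tr2, c(0, 10), "ML"), 0)
})

test_that("velocities follow the 3-4-5 path arithmetic and degenerate cases", {
  tr <- make_traj(c(0, 10, 20), x = c(0, 3, 3), y = c(0, 4, 4))
  expect_equal(velocity(tr, c(0, 20), "ML"), 15)
  expect_equal(velocity(tr, c(0, 20), "AP"), 20)
  expect_equal(velocity(tr, c(0, 20), "total"), 25)
  still <- make_traj(c(0, 10, 20), x = rep(1, 3), y = rep(2, 3))
  expect_equal(velocity(still, c(0, 20), "total"), 0)
  oned <- make_traj(c(0, 10, 20), x = rep(0, 3), y = c(0, 5, 9))
  expect_equal(velocity(oned, c(0, 20), "total"),
               velocity(oned, c(0, 20), "AP"))
  expect_true(is.na(velocity(tr, c(0, 5), "ML")))  # < 2 samples inside
})

test_that("increments belong to the interval holding the later sample", {
  tr <- make_traj(c(0, 10, 20, 30), x = c(0, 1, 3, 6), y = 0)
  # boundary at t = 10: the 0->1 increment belongs to [0,10], 1->3 to [10,20]
  expect_equal(velocity(tr, c(0, 10), "ML"), 100 * 1 / 10)
  expect_equal(velocity(tr, c(10, 30), "ML"), 100 * 5 / 20)
  # no increment is double-counted across the split
  whole <- velocity(tr, c(0, 30), "ML") * 30
  parts <- velocity(tr, c(0, 10), "ML") * 10 + velocity(tr, c(10, 30), "ML") * 20
  expect_equal(whole, parts)
})

test_that("net-displacement velocity variant uses endpoints only", {
  tr <- make_traj(c(0, 10, 20), x = c(0, 5, 1), y = 0)
  expect_equal(velocity(tr, c(0, 20), "ML", definition = "path"), 100 * 9 / 20)
  expect_equal(velocity(tr, c(0, 20), "ML", definition = "net"), 100 * 1 / 20)
})

test_that("velocity triangle inequality holds on random trajectories", {
  set.seed(11)
  for (i in 1:10) {
    nt <- 30
    tr <- make_traj(seq(0, 290, by = 10), x = cumsum(rnorm(nt)),
                    y = cumsum(rnorm(nt)))
    iv <- c(50, 210)
    vml <- velocity(tr, iv, "ML")
    vap <- velocity(tr, iv, "AP")
    vt <- velocity(tr, iv, "total")
    expect_gte(vt, max(vml, vap) - 1e-12)
    expect_lte(vt, vml + vap + 1e-12)
    # range over the whole stance dominates any subinterval
    expect_gte(displacement_range(tr, c(0, 290), "AP"),
               displacement_range(tr, iv, "AP"))
  }
})

test_that("resampling is linear interpolation at stance percentages", {
  tr <- make_traj(c(0, 100), x = c(0, 0), y = c(0, 100), foot_length = 100)
  rs <- resample_trajectory(tr, n_points = 100)
  expect_equal(rs$pct, seq(0, 100, length.out = 100))
  expect_equal(rs$y, seq(0, 100, length.out = 100), tolerance = 1e-9)
  rsn <- resample_trajectory(tr, n_points = 100, normalize = TRUE)
  expect_equal(rsn$y, seq(0, 100, length.out = 100), tolerance = 1e-9)
  # resampling an already-uniform 100-point trajectory is the identity
  tr2 <- make_traj(seq(0, 99), x = sin(1:100), y = cumsum(runif(100)))
  rs2 <- resample_trajectory(tr2, n_points = 100)
  expect_equal(rs2$x, tr2$x, tolerance = 1e-9)
  expect_equal(rs2$y, tr2$y, tolerance = 1e-9)
})

test_that("footfall parameters assemble one complete row per footfall", {
  co <- synth_footfall(seed = 5)
  ax <- estimate_axis(co$ff)
  ev <- normalize_events(detect_events(co$ff, ax))
  tr <- build_trajectory(co$ff, ax)
  row <- footfall_parameters(tr, ev)
  expect_equal(nrow(row), 1)
  durs <- unlist(row[paste0(c("ICP", "LCP", "FFP", "IPP", "LPP"),
                            "_dur_pct")])
  expect_equal(sum(durs), 100, tolerance = 1e-9)
  vels <- unlist(row[paste0("CbP_", c("velML_cms", "velAP_cms",
                                      "velTot_cms"))])
  expect_gte(vels[3], max(vels[1:2]))
  expect_lte(vels[3], vels[1] + vels[2])
})

test_that("analyze_recording yields a labeled table and logs exclusions", {
  cfg <- zero_noise(synth_config(seed = 8, n_steps = 3))
  g <- generate_recording(cfg)
  tab <- analyze_recording(g$recording, subject = "S1",
                           condition = "comfortable")
  expect_equal(nrow(tab), 3)
  expect_setequal(unique(tab$side), c("left", "right"))
  expect_true(all(c("stance_ms", "MON_pct", "LPP_velTot_cms",
                    "CbP_mlocAP_pct") %in% names(tab)))
  expect_s3_class(attr(tab, "exclusions"), "data.frame")
  # an empty recording gives an empty table with the full schema
  empty <- analyze_recording(mat_recording())
  expect_equal(nrow(empty), 0)
  expect_true(all(names(tab) %in% names(empty)))
})

test_that("trajectories of a mirrored left/right pair agree after side correction", {
  right <- synth_footfall(seed = 13, side = "right", theta_deg = 5)
  cells <- right$ff$cells
  frames <- right$ff$frames
  # exact raster mirror about the mat midline
  mcells <- cells; mcells$col <- 47 - mcells$col
  mframes <- frames; mframes$col <- 47 - mframes$col
  left <- make_footfall(mcells, frames = mframes, side = "left")
  axr <- estimate_axis(right$ff)
  axl <- estimate_axis(left)
  trr <- build_trajectory(right$ff, axr, side = "right")
  trl <- build_trajectory(left, axl, side = "left")
  expect_equal(trl$x, trr$x, tolerance = 1e-6)
  expect_equal(trl$y, trr$y, tolerance = 1e-6)
})
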