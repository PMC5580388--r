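# Data model, I/O, phase segmentation and distance/duration/speed accounting.

test_that("fix reading round-trips, enforces schema and time order", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("frog_id,timestamp,x_m,y_m,tadpoles,behavior",
               "F01,2015-02-01T08:00:00,312000,441000,8,transport",
               "F01,2015-02-01T08:30:00,312010,441005,8,transport",
               "F01,2015-02-01T09:00:00,312020,441004,,unknown"), f)
  fx <- read_fixes(f)
  expect_s3_class(fx, "frog_fixes")
  expect_equal(nrow(fx), 3)
  expect_equal(fx$tadpoles, c(8L, 8L, NA))
  expect_equal(fx$behavior[3], "unknown")

  # missing required column is named in the error
  writeLines(c("frog_id,timestamp,x_m", "F01,2015-02-01T08:00:00,312000"), f)
  expect_error(read_fixes(f), "y_m")

  # out-of-order timestamps rejected with offending rows
  writeLines(c("frog_id,timestamp,x_m,y_m",
               "F01,2015-02-01T09:00:00,312000,441000",
               "F01,2015-02-01T08:00:00,312010,441005"), f)
  expect_error(read_fixes(f), "strictly increasing")

  # longitude/latitude-looking coordinates refused
  writeLines(c("frog_id,timestamp,x_m,y_m",
               "F01,2015-02-01T08:00:00,-52.58,3.99",
               "F01,2015-02-01T08:30:00,-52.57,3.98"), f)
  expect_error(read_fixes(f), "project")
})

test_that("a written synthetic track reads back identically", {
  cfg <- sim_config(seed = 11, n_frogs = 1)
  ls <- build_landscape(cfg)
  fx <- simulate_transport(cfg, ls, "F01")$fixes
  f <- tempfile(fileext = ".csv")
  write_fixes(fx, f)
  back <- read_fixes(f)
  expect_equal(back$frog_id, fx$frog_id)
  expect_equal(as.numeric(back$t), as.numeric(fx$t))
  expect_equal(back$x, fx$x, tolerance = 1e-9)
  expect_equal(back$y, fx$y, tolerance = 1e-9)
  expect_equal(back$tadpoles, fx$tadpoles)
  expect_equal(back$behavior, fx$behavior)
})

test_that("territory centre is the centroid of territorial captures only", {
  expect_equal(unname(territory_center(rbind(c(0, 0), c(2, 0), c(1, 3)))$center),
               c(1, 1))
  # non-territorial points are ignored
  caps <- data.frame(x = c(5, 0, 9, 3, 7, 1), y = c(5, 0, 2, 8, 1, 4),
                     territorial = c(TRUE, rep(FALSE, 5)))
  tc <- territory_center(caps)
  expect_equal(unname(tc$center), c(5, 5))
  expect_equal(tc$n_captures, 1)
  expect_error(territory_center(caps, territorial = rep(FALSE, 6)),
               "no territorial captures")
})

test_that("centroid of many scattered captures recovers the true centre", {
  set.seed(42)
  pts <- cbind(rnorm(200, 10, 1), rnorm(200, 20, 1))
  tc <- territory_center(pts)
  expect_lt(sqrt(sum((tc$center - c(10, 20))^2)), 0.3)
})

test_that("path length matches brute force and bounds the chord", {
  expect_equal(path_length(make_traj(c(0, 1, 2), c(0, 0, 0),
                                     rbind(c(0, 0), c(2, 0)))), 2)
  expect_equal(path_length(make_traj(c(0, 3, 3), c(0, 0, 4),
                                     rbind(c(0, 0), c(3, 4)))), 7)
  set.seed(1)
  for (r in 1:50) {
    x <- rnorm(50, sd = 20); y <- rnorm(50, sd = 20)
    tr <- make_traj(x, y, rbind(c(x[1], y[1]), c(x[50], y[50])))
    expect_equal(path_length(tr), bf_path_length(x, y), tolerance = 1e-9)
    chord <- sqrt((x[50] - x[1])^2 + (y[50] - y[1])^2)
    expect_gte(path_length(tr), chord)
  }
  # equality branch: collinear monotone fixes
  tr <- make_traj(c(0, 1, 4, 9), c(0, 2, 8, 18),
                  rbind(c(0, 0), c(9, 18)))
  expect_equal(path_length(tr), sqrt(9^2 + 18^2), tolerance = 1e-12)
  expect_error(path_length(matrix(c(0, 0), nrow = 1)), "at least 2")
})

test_that("interpolated start is the chord and never exceeds a true path", {
  terr <- territory_center(rbind(c(0, 0)))
  expect_equal(interpolate_start(terr, c(3, 4)), 5)
  expect_equal(interpolate_start(terr, c(0, 0)), 0)
  set.seed(7)
  for (r in 1:100) {
    # random pre-encounter walk from the origin
    steps <- matrix(rnorm(20, sd = 2), ncol = 2)
    pos <- apply(steps, 2, cumsum)
    true_len <- bf_path_length(c(0, pos[, 1]), c(0, pos[, 2]))
    expect_lte(interpolate_start(terr, pos[10, ]), true_len + 1e-12)
  }
})

test_that("active duration excludes twelve hours per night spanned", {
  w <- daylight_window()
  mk <- function(t0, t1) {
    make_traj(c(0, 1), c(0, 0), rbind(c(0, 0), c(1, 0)),
              phase = "full") -> tr
    tr$fixes$t <- as.POSIXct(c(t0, t1), tz = "UTC")
    tr
  }
  expect_equal(active_duration(mk("2015-02-01 09:00", "2015-02-01 14:00"), w), 5)
  expect_equal(active_duration(mk("2015-02-01 10:00", "2015-02-02 10:00"), w), 12)
  tr <- mk("2015-02-01 18:00", "2015-02-03 08:00")
  expect_equal(active_duration(tr, w), 14)
  expect_equal(active_duration(tr, w),
               bf_active_hours(tr$fixes$t[1], tr$fixes$t[2]))
  # brute-force agreement on random day-spanning pairs
  set.seed(3)
  for (r in 1:30) {
    t0 <- as.POSIXct("2015-02-01 07:00", tz = "UTC") +
      round(runif(1, 0, 720)) * 60
    t1 <- t0 + round(runif(1, 10, 4000)) * 60
    # clamp both ends into the window as the package would
    m1 <- as.POSIXlt(t1, tz = "UTC")$hour + as.POSIXlt(t1, tz = "UTC")$min / 60
    if (m1 < 7) t1 <- t1 + (7 - m1) * 3600
    if (m1 > 19) t1 <- t1 - (m1 - 19) * 3600
    tr <- mk(format(t0), format(t1))
    expect_equal(active_duration(tr, w),
                 bf_active_hours(tr$fixes$t[1], tr$fixes$t[2]),
                 tolerance = 1e-9)
  }
  # out-of-window fix is clamped with a warning
  tr <- mk("2015-02-01 06:00", "2015-02-01 14:00")
  expect_warning(d <- active_duration(tr, w), "clamped")
  expect_equal(d, 7)
})

test_that("mean speed reproduces the worked per-phase examples", {
  tr <- make_traj(c(0, 55.16), c(0, 0), rbind(c(0, 0), c(55.16, 0)),
                  t = as.POSIXct(c("2015-02-01 08:00:00",
                                   "2015-02-01 11:04:48"), tz = "UTC"))
  expect_equal(round(mean_speed(tr), 2), 17.91)
  tr2 <- make_traj(c(0, 22.16), c(0, 0), rbind(c(0, 0), c(22.16, 0)),
                   t = as.POSIXct(c("2015-02-01 08:00", "2015-02-01 09:00"),
                                  tz = "UTC"))
  expect_equal(mean_speed(tr2), 22.16)
  # loop: speed uses path length, not displacement
  loop <- make_traj(c(0, 5, 0), c(0, 0, 0), rbind(c(0, 0), c(0.001, 0)),
                    t = T0 + c(0, 3600, 7200))
  expect_equal(mean_speed(loop), 5)
})

test_that("per-step speeds handle nights and reject duplicate times", {
  tr <- make_traj(c(0, 10), c(0, 0), rbind(c(0, 0), c(10, 0)),
                  t = T0 + c(0, 1800))
  expect_equal(step_speeds(tr), 20)
  stat <- make_traj(c(0, 0, 0), c(0, 0, 0), rbind(c(0, 0), c(1, 0)))
  expect_equal(step_speeds(stat), c(0, 0))
  # step across a night uses night-excluded duration
  tr2 <- make_traj(c(0, 12), c(0, 0), rbind(c(0, 0), c(12, 0)),
                   t = as.POSIXct(c("2015-02-01 18:00", "2015-02-02 08:00"),
                                  tz = "UTC"))
  expect_equal(step_speeds(tr2), 12 / 2)
  dup <- make_traj(c(0, 1), c(0, 0), rbind(c(0, 0), c(1, 0)),
                   t = c(T0, T0))
  expect_error(step_speeds(dup), "duplicate")
})

test_that("durations partition additively at the shared splitting fix", {
  s <- sim_one(5)
  w <- daylight_window()
  # full span = first TT fix through last HT fix (the split fix is shared)
  n_tt <- nrow(s$seg$TT$fixes)
  n_ht <- nrow(s$seg$HT$fixes)
  idx <- seq_len(n_tt + n_ht - 1)
  full <- trajectory(s$run$fixes[idx, ], rbind(c(0, 0), c(1, 1)),
                     phase = "full")
  expect_equal(active_duration(s$seg$TT, w) + active_duration(s$seg$HT, w),
               active_duration(full, w), tolerance = 1 / 3600)
})

test_that("speeds are invariant under rigid motion of the coordinates", {
  set.seed(9)
  x <- cumsum(rnorm(20)); y <- cumsum(rnorm(20))
  tr <- make_traj(x, y, rbind(c(x[1], y[1]), c(x[20], y[20])))
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- cbind(x, y) %*% R + matrix(c(120, -40), 20, 2, byrow = TRUE)
  tr2 <- make_traj(xy2[, 1], xy2[, 2],
                   rbind(xy2[1, ], xy2[20, ]))
  expect_equal(mean_speed(tr), mean_speed(tr2), tolerance = 1e-9)
  expect_equal(step_speeds(tr), step_speeds(tr2), tolerance = 1e-9)
})

test_that("phase segmentation cuts at the last deposition", {
  # 10 fixes walking east, pools at fix 6 position
  x <- seq(0, 90, by = 10); y <- rep(0, 10)
  fx <- make_fixes(x, y, tadpoles = c(rep(8L, 5), rep(0L, 5)))
  pools <- data.frame(pool_id = "P01", x = 50, y = 0, kind = "artificial",
                      status = "available", stringsAsFactors = FALSE)
  class(pools) <- c("frog_pools", "data.frame")
  v <- detect_visits(fx, pools, r_visit = 1)
  v <- infer_depositions(v, fx)
  terr <- territory_center(rbind(c(90, 0)))
  seg <- segment_phases(fx, v, terr, r_home = 5)
  expect_equal(nrow(seg$TT$fixes), 6)
  expect_equal(seg$TT$fixes$x, x[1:6])
  expect_equal(nrow(seg$HT$fixes), 5)   # shared splitting fix
  expect_equal(seg$HT$fixes$x[1], 50)
  expect_true(seg$HT$complete)
  # last TT waypoint is the deposition site, last HT waypoint the territory
  expect_equal(seg$TT$waypoints[nrow(seg$TT$waypoints), ], c(50, 0))
  expect_equal(seg$HT$waypoints[2, ], unname(terr$center))

  # two depositions: TT ends at the second one
  x2 <- seq(0, 90, by = 10)
  fx2 <- make_fixes(x2, y, tadpoles = c(8L, 8L, 8L, 4L, 4L, 4L, 0L, 0L, 0L, 0L))
  pools2 <- data.frame(pool_id = c("P01", "P02"), x = c(30, 60), y = c(0, 0),
                       kind = "artificial", status = "available",
                       stringsAsFactors = FALSE)
  class(pools2) <- c("frog_pools", "data.frame")
  v2 <- infer_depositions(detect_visits(fx2, pools2, r_visit = 1), fx2)
  seg2 <- segment_phases(fx2, v2, terr, r_home = 5)
  expect_equal(nrow(seg2$TT$fixes), 7)
  expect_equal(seg2$TT$waypoints[nrow(seg2$TT$waypoints), ], c(60, 0))

  # never returns: HT incomplete
  seg3 <- segment_phases(fx, v, territory_center(rbind(c(500, 500))),
                         r_home = 5)
  expect_false(seg3$HT$complete)
  # no deposition: error
  v0 <- v; v0$deposition <- FALSE
  expect_error(segment_phases(fx, v0, terr), "no deposition")
})

test_that("segmentation recovers simulator truth exactly", {
  for (s in c(2, 13, 21)) {
    r <- sim_one(s)
    expect_equal(nrow(r$seg$TT$fixes), r$run$truth$split_fix)
    expect_equal(r$seg$HT$fixes$t[1],
                 r$run$fixes$t[r$run$truth$split_fix])
  }
})
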