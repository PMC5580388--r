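# Straightness, angular and perpendicular deviation, Rayleigh test.

test_that("straightness coefficient matches the textbook cases", {
  tr <- make_traj(c(0, 3, 3), c(0, 0, 4), rbind(c(0, 0), c(3, 4)))
  expect_equal(straightness_coefficient(tr), 5 / 7)
  expect_equal(straightness_coefficient(tr, anchor = "waypoints"), 5 / 7)
  # collinear fixes from waypoint to waypoint: SC = 1
  tr2 <- make_traj(c(0, 2, 5, 9), c(0, 0, 0, 0), rbind(c(0, 0), c(9, 0)))
  expect_equal(straightness_coefficient(tr2), 1)
  # fixes equal to the waypoint chain: SC = 1 in both conventions
  tr3 <- make_traj(c(0, 10, 10), c(0, 0, 15),
                   rbind(c(0, 0), c(10, 0), c(10, 15)),
                   waypoint_times = T0 + c(0, 1800, 3600))
  expect_equal(straightness_coefficient(tr3), 1)
  expect_equal(straightness_coefficient(tr3, anchor = "waypoints"), 1)
  expect_error(straightness_coefficient(make_traj(c(0, 0), c(0, 0),
                                                  rbind(c(0, 0), c(1, 0)))),
               "zero path length")
})

test_that("fix-anchored straightness equals an independent oracle on random tracks", {
  set.seed(21)
  for (r in 1:200) {
    n <- sample(5:30, 1)
    x <- cumsum(rnorm(n, 1)); y <- cumsum(rnorm(n))
    wp <- rbind(c(x[1], y[1]),
                c(x[ceiling(n / 2)] + rnorm(1, 0, .3),
                  y[ceiling(n / 2)] + rnorm(1, 0, .3)),
                c(x[n], y[n]))
    tr <- make_traj(x, y, wp, waypoint_times = T0 + c(0, (n %/% 2), n) * 1800)
    expect_equal(straightness_coefficient(tr),
                 bf_sc(x, y, wp[, 1], wp[, 2]), tolerance = 1e-12)
    expect_lte(straightness_coefficient(tr), 1)
  }
})

test_that("angular deviation handles the wrap and matches brute force", {
  tr <- make_traj(c(0, 1), c(0, 1), rbind(c(0, 0), c(10, 0)))
  expect_equal(as.numeric(angular_deviation(tr)), 45)
  # aiming exactly at the goal: 0 degrees
  tr2 <- make_traj(c(0, 2, 7), c(0, 0, 0), rbind(c(0, 0), c(10, 0)))
  expect_equal(as.numeric(angular_deviation(tr2)), 0)
  # circular wrap: 350 vs 10 deg differ by 20, not 340
  tr3 <- make_traj(c(0, cos(pi / 18)), c(0, sin(pi / 18)),
                   rbind(c(0, 0), c(10, -10 * tan(pi / 18))))
  expect_equal(as.numeric(angular_deviation(tr3)), 20, tolerance = 1e-9)
  # fix coinciding with its goal is skipped with a warning
  tr4 <- make_traj(c(0, 10, 11), c(0, 0, 0), rbind(c(0, 0), c(10, 0)))
  expect_warning(a <- angular_deviation(tr4), "coincide")
  expect_equal(as.numeric(a), 0)
  # brute force on random single-goal tracks
  set.seed(4)
  for (r in 1:100) {
    n <- sample(4:20, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    tr <- make_traj(x, y, rbind(c(x[1], y[1]), c(50, 30)))
    expect_equal(as.numeric(angular_deviation(tr)),
                 bf_ang_dev(x, y, 50, 30), tolerance = 1e-9)
  }
})

test_that("perpendicular deviation measures to the chord line", {
  tr <- make_traj(c(0, 1, 2), c(0, 1, 0), rbind(c(0, 0), c(2, 0)))
  expect_equal(as.numeric(perpendicular_deviation(tr)), 1 / 3)
  on_line <- make_traj(c(0, 1, 2), c(0, 0, 0), rbind(c(0, 0), c(2, 0)))
  expect_equal(as.numeric(perpendicular_deviation(on_line)), 0)
  expect_error(perpendicular_deviation(
    make_traj(c(0, 1), c(0, 0), rbind(c(0, 0), c(0, 0)))), "degenerate")
  # oracle equality on random fixes
  set.seed(8)
  x <- runif(100, -50, 50); y <- runif(100, -50, 50)
  tr <- make_traj(x, y, rbind(c(-3, 7), c(40, -20)))
  got <- attr(perpendicular_deviation(tr), "values")
  want <- bf_point_line(x, y, -3, 7, 40, -20)
  expect_equal(got, want, tolerance = 1e-9)
  # clamped variant never smaller than the infinite-line distance
  gotc <- attr(perpendicular_deviation(tr, clamp = TRUE), "values")
  expect_true(all(gotc >= got - 1e-12))
})

test_that("step headings follow the east-zero counter-clockwise convention", {
  expect_equal(step_headings(make_traj(c(0, 1), c(0, 0),
                                       rbind(c(0, 0), c(1, 0)))), 0)
  expect_equal(step_headings(make_traj(c(0, 0), c(0, 2),
                                       rbind(c(0, 0), c(0, 2)))), 90)
  expect_equal(step_headings(make_traj(c(0, -1), c(0, -1),
                                       rbind(c(0, 0), c(-1, -1)))), 225)
  # zero-length steps omitted
  expect_equal(length(step_headings(make_traj(c(0, 0, 1), c(0, 0, 0),
                                              rbind(c(0, 0), c(1, 0))))), 1)
  expect_error(step_headings(make_traj(c(0, 0), c(0, 0),
                                       rbind(c(0, 0), c(1, 0)))),
               "no movement")
})

test_that("Rayleigh test endpoints and statistic are exact", {
  r <- rayleigh_test(rep(33, 10))
  expect_equal(r$rbar, 1)
  expect_equal(r$z, 10)
  expect_lt(r$p, 0.001)
  u <- rayleigh_test(c(0, 90, 180, 270))
  expect_equal(u$rbar, 0, tolerance = 1e-12)
  expect_equal(u$p, 1)
  expect_error(rayleigh_test(c(0, 10, 20)), "too few")
})

test_that("Rayleigh p agrees with a Monte-Carlo permutation null", {
  set.seed(31)
  for (r in 1:8) {
    n <- sample(5:50, 1)
    kap <- runif(1, 0, 1.2)
    ang <- rvonmises(n, runif(1, 0, 2 * pi), kap) * 180 / pi
    p_series <- rayleigh_test(ang)$p
    p_mc <- mc_rayleigh_p(ang, reps = 20000)
    expect_lt(abs(p_series - p_mc), 0.01)
  }
})

test_that("precision statistics are invariant under rigid motion", {
  set.seed(12)
  x <- cumsum(rnorm(15, 1)); y <- cumsum(rnorm(15))
  wp <- rbind(c(x[1], y[1]), c(x[15], y[15]))
  tr <- make_traj(x, y, wp)
  th <- -1.2; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- cbind(x, y) %*% R + matrix(c(-300, 77), 15, 2, byrow = TRUE)
  tr2 <- make_traj(xy2[, 1], xy2[, 2], wp %*% R +
                     matrix(c(-300, 77), 2, 2, byrow = TRUE))
  expect_equal(straightness_coefficient(tr), straightness_coefficient(tr2),
               tolerance = 1e-9)
  expect_equal(as.numeric(angular_deviation(tr)),
               as.numeric(angular_deviation(tr2)), tolerance = 1e-9)
  expect_equal(as.numeric(perpendicular_deviation(tr)),
               as.numeric(perpendicular_deviation(tr2)), tolerance = 1e-9)
})

test_that("short trajectories are excluded from the directionality analysis", {
  tr <- make_traj(c(0, 3, 3), c(0, 0, 4), rbind(c(0, 0), c(3, 4)))
  row <- precision_summary(tr)          # 3 locations: filtered out
  expect_false(row$included)
  expect_true(is.na(row$sc))
  tr4 <- make_traj(c(0, 1, 3, 6), c(0, 1, 0, 1), rbind(c(0, 0), c(6, 1)))
  row4 <- precision_summary(tr4)
  expect_true(row4$included)
  expect_false(is.na(row4$sc))
})

test_that("goal-relative deviation angles centre on zero for straight walks", {
  tr <- make_traj(c(0, 2, 5, 9), c(0, 0, 0, 0), rbind(c(0, 0), c(9, 0)))
  expect_equal(deviation_angles(tr), c(0, 0, 0))
})
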