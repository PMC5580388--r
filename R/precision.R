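# Goal-directed movement precision statistics and the Rayleigh test.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# Absolute bearing from point a to point b, degrees in [0, 360),
# east = 0, counter-clockwise.
.bearing_deg <- function(a, b) {
  (.deg(atan2(b[2] - a[2], b[1] - a[1]))) %% 360
}

# Map an angular difference (deg) onto [0, 180].
.wrap180 <- function(d) abs(((d + 180) %% 360) - 180)

#' Absolute step headings of a trajectory
#'
#' One bearing per nonzero fix-to-fix step, in degrees with east = 0 and
#' angles increasing counter-clockwise; zero-length steps are omitted.
#'
#' @param traj a `frog_trajectory`.
#' @return numeric vector of bearings in `[0, 360)`.
#' @export
step_headings <- function(traj) {
  xy <- .traj_xy(traj)
  if (nrow(xy) < 2) stop("step_headings needs at least 2 fixes", call. = FALSE)
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  nz <- dx != 0 | dy != 0
  if (!any(nz)) stop("no movement: all steps have zero length", call. = FALSE)
  (.deg(atan2(dy[nz], dx[nz]))) %% 360
}

#' Assign a goal waypoint to every fix
#'
#' During multi-pool tadpole transport each fix's goal is the next deposition
#' site the frog subsequently reached (chronological attribution via the
#' waypoint attainment times); during homing the goal is the territory centre
#' throughout.
#'
#' @param traj a `frog_trajectory` whose waypoints carry attainment times
#'   (`waypoint_times`); a two-waypoint trajectory needs no times (the goal
#'   is always the second waypoint).
#' @return integer vector, one goal waypoint index (>= 2) per fix.
#' @export
assign_goals <- function(traj) {
  n <- nrow(traj$fixes)
  nw <- nrow(traj$waypoints)
  if (nw == 2) return(rep(2L, n))
  if (is.null(traj$waypoint_times)) {
    stop("waypoints are not on the fix time axis: waypoint_times required ",
         "for more than two waypoints", call. = FALSE)
  }
  wt <- as.numeric(traj$waypoint_times)
  vapply(as.numeric(traj$fixes$t), function(ti) {
    j <- which(wt > ti & seq_len(nw) >= 2)
    if (length(j)) min(j) else nw
  }, integer(1))
}

#' Straightness coefficient of a trajectory
#'
#' Ratio of the straight-line distance to the goal(s) — the piecewise chord
#' through the ordered waypoints — to the realised path length. Ranges over
#' (0, 1], 1 indicating a perfectly straight path.
#'
#' With `anchor = "fixes"` (the default) the chord vertices are anchored to
#' the realised track: the first and last vertex are the first and last fix,
#' and each intermediate waypoint is represented by the fix closest to it.
#' Because every vertex then lies on the path, in order, the coefficient is
#' structurally confined to (0, 1] even under fix measurement noise.
#' `anchor = "waypoints"` uses the ideal waypoint coordinates themselves
#' (the textbook definition); with noisy fixes, or a track cut at the
#' returned-home fix short of the territory centre, that chord can slightly
#' exceed the observed path, in which case values exceeding 1 by less than
#' 1e-9 are clipped and larger excesses warn.
#'
#' @param traj a `frog_trajectory`.
#' @param anchor `"fixes"` or `"waypoints"` (see Details).
#' @return the straightness coefficient.
#' @examples
#' f <- data.frame(frog_id = "a",
#'                 t = as.POSIXct("2015-02-01 08:00", tz = "UTC") + 0:2 * 1800,
#'                 x = c(0, 3, 3), y = c(0, 0, 4))
#' sc <- straightness_coefficient(trajectory(f, rbind(c(0, 0), c(3, 4)), "TT"))
#' stopifnot(all.equal(sc, 5 / 7))
#' @export
straightness_coefficient <- function(traj, anchor = c("fixes", "waypoints")) {
  anchor <- match.arg(anchor)
  den <- path_length(traj)
  if (den == 0) stop("zero path length; straightness undefined", call. = FALSE)
  if (anchor == "waypoints") {
    num <- sum(.seg_lengths(traj$waypoints))
  } else {
    xy <- .traj_xy(traj)
    n <- nrow(xy)
    w <- traj$waypoints
    nw <- nrow(w)
    vidx <- 1L
    if (nw > 2) {
      for (j in 2:(nw - 1)) {
        cand <- which(seq_len(n) > vidx[length(vidx)] & seq_len(n) < n)
        if (!length(cand)) next
        d <- sqrt((xy[cand, 1] - w[j, 1])^2 + (xy[cand, 2] - w[j, 2])^2)
        vidx <- c(vidx, cand[which.min(d)])
      }
    }
    vidx <- c(vidx, n)
    num <- sum(.seg_lengths(xy[vidx, , drop = FALSE]))
  }
  sc <- num / den
  if (sc > 1 && sc <= 1 + 1e-9) sc <- 1
  if (sc > 1) {
    warning("straightness coefficient exceeds 1: the realised path is ",
            "shorter than the waypoint chord; consider anchor = \"fixes\"")
  }
  sc
}

# Per-fix absolute angular deviations (deg in [0, 180]) between the ideal
# bearing (fix -> goal) and the realised bearing (fix -> next fix).
.angular_deviations <- function(traj, goals = assign_goals(traj)) {
  xy <- .traj_xy(traj)
  n <- nrow(xy)
  out <- rep(NA_real_, n - 1)
  skipped_goal <- 0L
  for (i in seq_len(n - 1)) {
    p <- xy[i, ]; q <- xy[i + 1, ]
    if (all(p == q)) next   # zero-length step
    g <- traj$waypoints[goals[i], ]
    if (.dist2(p, g) < 1e-12) { skipped_goal <- skipped_goal + 1L; next }
    out[i] <- .wrap180(.bearing_deg(p, g) - .bearing_deg(p, q))
  }
  if (skipped_goal > 0) {
    warning(sprintf("%d fix(es) coincide with their goal; ideal direction undefined, skipped",
                    skipped_goal))
  }
  out
}

#' Mean angular deviation from the ideal direction
#'
#' For every non-final fix, the absolute circular difference between the
#' ideal direction (bearing from the fix to its current goal) and the
#' realised direction (bearing to the next fix), mapped to `[0, 180]`
#' degrees; the trajectory value is the mean. Zero-length steps are skipped;
#' a fix coinciding with its goal is skipped with a warning.
#'
#' @param traj a `frog_trajectory`.
#' @param goals per-fix goal waypoint indices, defaulting to
#'   [assign_goals()].
#' @return mean absolute angular deviation in degrees, with the per-fix
#'   values in attribute `"values"`.
#' @export
angular_deviation <- function(traj, goals = assign_goals(traj)) {
  v <- .angular_deviations(traj, goals)
  structure(mean(v, na.rm = TRUE), values = v)
}

#' Mean perpendicular deviation from the straight path
#'
#' For every fix, the perpendicular distance to the infinite line through its
#' current chord segment (the waypoint pair whose goal is assigned to that
#' fix); the trajectory value is the mean. Set `clamp = TRUE` to measure to
#' the clamped segment instead of the infinite line.
#'
#' @inheritParams angular_deviation
#' @param clamp measure to the clamped segment rather than the infinite line.
#' @return mean perpendicular deviation in metres, per-fix values in
#'   attribute `"values"`.
#' @export
perpendicular_deviation <- function(traj, goals = assign_goals(traj),
                                    clamp = FALSE) {
  xy <- .traj_xy(traj)
  w <- traj$waypoints
  v <- vapply(seq_len(nrow(xy)), function(i) {
    g <- goals[min(i, length(goals))]
    .point_line_dist(xy[i, ], w[g - 1, ], w[g, ], clamp = clamp)
  }, numeric(1))
  structure(mean(v), values = v)
}

#' Goal-relative deviation angles of a trajectory
#'
#' Signed angular deviations (degrees in `(-180, 180]`) of each realised step
#' from the ideal direction towards the current goal. Pooling these across
#' trajectories of a phase (each trajectory's ideal direction mapped to 0)
#' gives the angle set for the phase-level Rayleigh test.
#'
#' @inheritParams angular_deviation
#' @return numeric vector of signed deviations, zero-length and
#'   goal-coincident steps dropped.
#' @export
deviation_angles <- function(traj, goals = assign_goals(traj)) {
  xy <- .traj_xy(traj)
  n <- nrow(xy)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    p <- xy[i, ]; q <- xy[i + 1, ]
    if (all(p == q)) next
    g <- traj$waypoints[goals[i], ]
    if (.dist2(p, g) < 1e-12) next
    d <- (.bearing_deg(p, q) - .bearing_deg(p, g)) %% 360
    if (d > 180) d <- d - 360
    out <- c(out, d)
  }
  out
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is concentrated around a common direction
#' using the mean resultant length \eqn{\bar R} of the unit vectors. The
#' statistic is \eqn{Z = n \bar R^2} and the p-value uses the standard
#' series approximation
#' \deqn{p = e^{-Z} [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]}
#' clamped to `[0, 1]`.
#'
#' @param angles_deg numeric vector of angles in degrees (n >= 4).
#' @return a `rayleigh_test` list with `n`, `rbar`, `z` and `p`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 4) stop("too few angles: Rayleigh test needs n >= 4", call. = FALSE)
  a <- .rad(angles_deg)
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  structure(list(n = n, rbar = rbar, z = z, p = min(max(p, 0), 1)),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, rbar = %.3f, Z = %.3f, p = %.4g\n",
              x$n, x$rbar, x$z, x$p))
  invisible(x)
}

#' Per-trajectory precision summary
#'
#' Computes the three goal-directed precision statistics (straightness
#' coefficient, mean absolute angular deviation, mean perpendicular
#' deviation) plus a Rayleigh test on the trajectory's goal-relative
#' deviation angles. Trajectories with `min_locations` or fewer fixes are
#' excluded from the directionality analysis: the row is returned with the
#' statistics set to `NA` and `included = FALSE`.
#'
#' @param traj a `frog_trajectory`.
#' @param min_locations minimum fix count for inclusion; the default 4
#'   implements the "more than three locations" filter.
#' @return a one-row data frame: `frog_id`, `phase`, `n_locations`,
#'   `included`, `sc`, `mean_ang_dev_deg`, `mean_perp_dev_m`,
#'   `rayleigh_rbar`, `rayleigh_p`.
#' @export
precision_summary <- function(traj, min_locations = 4) {
  n <- nrow(traj$fixes)
  row <- data.frame(frog_id = traj$frog_id, phase = traj$phase,
                    n_locations = n, included = n >= min_locations,
                    sc = NA_real_, mean_ang_dev_deg = NA_real_,
                    mean_perp_dev_m = NA_real_,
                    rayleigh_rbar = NA_real_, rayleigh_p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!row$included) return(row)
  goals <- assign_goals(traj)
  row$sc <- straightness_coefficient(traj)
  row$mean_ang_dev_deg <- as.numeric(angular_deviation(traj, goals))
  row$mean_perp_dev_m <- as.numeric(perpendicular_deviation(traj, goals))
  ang <- deviation_angles(traj, goals)
  if (length(ang) >= 4) {
    r <- rayleigh_test(ang)
    row$rayleigh_rbar <- r$rbar
    row$rayleigh_p <- r$p
  }
  row
}
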