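# Trajectory container, phase segmentation and distance/duration/speed
# accounting.

#' Daylight activity window
#'
#' The frogs are strictly diurnal and were only tracked between the start and
#' end of the daylight window; night hours are excluded from all duration and
#' speed accounting.
#'
#' @param day_start,day_end clock times as `"HH:MM"` strings.
#' @return a `daylight_window` list with `start_min`, `end_min` (minutes past
#'   midnight) and `night_hours` (= 24 h minus the window length).
#' @export
daylight_window <- function(day_start = "07:00", day_end = "19:00") {
  p <- function(s) {
    h <- as.integer(substr(s, 1, 2)); m <- as.integer(substr(s, 4, 5))
    h * 60 + m
  }
  s <- p(day_start); e <- p(day_end)
  if (!(s < e)) stop("day_start must precede day_end", call. = FALSE)
  structure(list(start_min = s, end_min = e,
                 night_hours = 24 - (e - s) / 60),
            class = "daylight_window")
}

# Minutes past midnight of a POSIXct (UTC-as-local-clock convention).
.min_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

# Clamp timestamps into the daylight window; out-of-window times (clock
# drift) are moved to the nearest window edge of the same day.
.clamp_to_window <- function(t, window, warn = TRUE) {
  m <- .min_of_day(t)
  lo <- m < window$start_min
  hi <- m > window$end_min
  if (any(lo | hi) && warn) {
    warning(sprintf("%d fix time(s) outside the %02d:%02d-%02d:%02d window; clamped to the window edge",
                    sum(lo | hi),
                    window$start_min %/% 60, window$start_min %% 60,
                    window$end_min %/% 60, window$end_min %% 60))
  }
  t[lo] <- t[lo] + (window$start_min - m[lo]) * 60
  t[hi] <- t[hi] - (m[hi] - window$end_min) * 60
  t
}

#' Construct a trajectory
#'
#' A trajectory is an ordered fix sequence for one frog in one movement
#' phase, together with the waypoints defining its ideal (straight) route:
#' for tadpole transport (TT) the first fix followed by each visited
#' deposition site in visit order; for homing (HT) the last deposition site
#' followed by the territory centre.
#'
#' @param fixes a fixes data frame (single frog) with columns `t`, `x`, `y`.
#' @param waypoints numeric matrix (>= 2 rows, columns x, y) of ideal-route
#'   waypoints.
#' @param phase `"TT"`, `"HT"` or `"full"`.
#' @param frog_id frog identifier; defaults to the one in `fixes`.
#' @param waypoint_times optional POSIXct vector, one per waypoint, giving
#'   the time each waypoint was attained; used to assign per-fix goals.
#' @param interpolated_start_m straight-line length (m) of the unobserved
#'   track section from the territory centre to the first fix (TT only).
#' @param complete logical; `FALSE` marks a homing trajectory on which the
#'   frog was never observed back inside its territory.
#' @return a `frog_trajectory` object.
#' @export
trajectory <- function(fixes, waypoints, phase = c("TT", "HT", "full"),
                       frog_id = NULL, waypoint_times = NULL,
                       interpolated_start_m = NA_real_, complete = TRUE) {
  phase <- match.arg(phase)
  if (nrow(fixes) < 2) stop("a trajectory needs at least 2 fixes", call. = FALSE)
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2) stop("at least 2 waypoints required", call. = FALSE)
  if (!is.null(waypoint_times) && length(waypoint_times) != nrow(waypoints)) {
    stop("waypoint_times must match the number of waypoints", call. = FALSE)
  }
  structure(
    list(frog_id = frog_id %||% fixes$frog_id[1], phase = phase,
         fixes = as.data.frame(fixes), waypoints = unname(waypoints),
         waypoint_times = waypoint_times,
         interpolated_start_m = interpolated_start_m, complete = complete),
    class = "frog_trajectory"
  )
}

#' @export
print.frog_trajectory <- function(x, ...) {
  cat(sprintf("<%s trajectory> frog %s: %d fixes, %d waypoints, %.1f m%s\n",
              x$phase, x$frog_id, nrow(x$fixes), nrow(x$waypoints),
              path_length(x), if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

.traj_xy <- function(traj) {
  if (inherits(traj, "frog_trajectory")) cbind(traj$fixes$x, traj$fixes$y)
  else as.matrix(traj)
}

#' Realised path length of a trajectory
#'
#' Sum of Euclidean lengths of consecutive fix-to-fix segments; always at
#' least the straight chord between the first and the last fix.
#'
#' @param traj a `frog_trajectory`, or an n x 2 coordinate matrix.
#' @return length in metres.
#' @export
path_length <- function(traj) {
  xy <- .traj_xy(traj)
  if (nrow(xy) < 2) stop("path_length needs at least 2 fixes", call. = FALSE)
  sum(.seg_lengths(xy))
}

#' Straight-line estimate of the unobserved pre-encounter track
#'
#' Frogs were usually first encountered already on their way to the pools;
#' the missing section from the territory centre to the first fix is
#' approximated by its straight chord. This is a minimum-distance estimate:
#' it can never exceed the length of any actual path.
#'
#' @param territory a `frog_territory` (or a length-2 numeric centre).
#' @param first_fix a one-row fixes data frame, or a length-2 numeric point.
#' @return chord length in metres.
#' @export
interpolate_start <- function(territory, first_fix) {
  ctr <- if (inherits(territory, "frog_territory")) territory$center
         else as.numeric(territory)
  p <- if (is.data.frame(first_fix)) c(first_fix$x[1], first_fix$y[1])
       else as.numeric(first_fix)
  .dist2(ctr, p)
}

# Night-excluded elapsed hours between two clock timestamps.
.active_hours <- function(t0, t1, window, warn = TRUE) {
  t0 <- .clamp_to_window(t0, window, warn = warn)
  t1 <- .clamp_to_window(t1, window, warn = warn)
  nights <- as.integer(as.Date(t1, tz = "UTC") - as.Date(t0, tz = "UTC"))
  h <- as.numeric(difftime(t1, t0, units = "hours")) -
    nights * window$night_hours
  pmax(h, 0)
}

#' Night-excluded active duration of a trajectory
#'
#' Elapsed time between the first and the last fix minus the full night
#' (outside the daylight window) for every night the track spans. Fixes
#' logged outside the daylight window are clamped to the window edge with a
#' warning.
#'
#' @param traj a `frog_trajectory`.
#' @param window a [daylight_window()].
#' @return duration in hours (>= 0).
#' @export
active_duration <- function(traj, window = daylight_window()) {
  t <- traj$fixes$t
  .active_hours(t[1], t[length(t)], window)
}

#' Mean movement speed over a trajectory
#'
#' Realised path length divided by the night-excluded active duration.
#' The numerator is the path length (not the net displacement), so a closed
#' loop still has positive speed.
#'
#' @inheritParams active_duration
#' @return speed in metres per hour.
#' @export
mean_speed <- function(traj, window = daylight_window()) {
  dur <- active_duration(traj, window)
  if (dur <= 0) stop("zero active duration; speed undefined", call. = FALSE)
  path_length(traj) / dur
}

#' Per-step speeds along a trajectory
#'
#' One value per consecutive fix pair; a step spanning a night uses the
#' night-excluded duration of that step.
#'
#' @inheritParams active_duration
#' @return numeric vector of speeds (m/h), length `nrow(fixes) - 1`.
#' @export
step_speeds <- function(traj, window = daylight_window()) {
  f <- traj$fixes
  if (nrow(f) < 2) stop("step_speeds needs at least 2 fixes", call. = FALSE)
  if (any(diff(as.numeric(f$t)) == 0)) {
    stop("duplicate timestamps in trajectory", call. = FALSE)
  }
  d <- .seg_lengths(cbind(f$x, f$y))
  n <- nrow(f)
  dur <- .active_hours(f$t[-n], f$t[-1], window)
  if (any(dur <= 0)) stop("zero-duration step", call. = FALSE)
  d / dur
}

#' Split a track into tadpole-transport and homing phases
#'
#' The tadpole-transport trajectory (TT) runs from the first fix through the
#' fix at the last deposition event; the homing trajectory (HT) runs from
#' that fix back to the first fix at which the frog is back in its territory
#' (within `r_home` of the territory centre). The splitting fix belongs to
#' both phases, so distances and durations partition exactly. If the frog is
#' never observed back home the HT is returned complete = FALSE rather than
#' silently truncated.
#'
#' TT waypoints are the first fix followed by the centre of every pool
#' visited up to (and including) the last deposition, in visit order; HT
#' waypoints are the last deposition site and the territory centre.
#'
#' @param fixes fixes data frame for one frog, sorted by time.
#' @param visits a visit-event data frame from [detect_visits()] +
#'   [infer_depositions()]; must contain at least one `deposition = TRUE`
#'   event with pool coordinates `pool_x`, `pool_y`.
#' @param territory the frog's `frog_territory`.
#' @param r_home radius (m) around the territory centre within which the frog
#'   counts as returned; default 7 m, the radius of a circle with the average
#'   defended territory area of about 151 m^2.
#' @return list with elements `TT` (a `frog_trajectory` or `NULL` when the
#'   frog was first encountered at the deposition site itself) and `HT`.
#' @export
segment_phases <- function(fixes, visits, territory, r_home = 7) {
  stopifnot(nrow(fixes) >= 2)
  dep <- visits[!is.na(visits$deposition) & visits$deposition, , drop = FALSE]
  if (nrow(dep) == 0) stop("no deposition event in visits", call. = FALSE)
  last_dep <- dep[which.max(as.numeric(dep$t_arrive)), , drop = FALSE]
  in_last <- which(fixes$t >= last_dep$t_arrive & fixes$t <= last_dep$t_depart)
  i_split <- if (length(in_last)) max(in_last) else
    max(which(fixes$t <= last_dep$t_depart))

  tt_visits <- visits[visits$t_arrive <= fixes$t[i_split], , drop = FALSE]
  tt_visits <- tt_visits[order(tt_visits$t_arrive), , drop = FALSE]
  # drop trailing non-deposition visits so the last waypoint is the last
  # deposition site
  keep <- tt_visits$t_arrive <= last_dep$t_arrive
  tt_visits <- tt_visits[keep, , drop = FALSE]

  interp <- interpolate_start(territory, fixes[1, ])

  TT <- NULL
  if (i_split >= 2) {
    wp <- rbind(c(fixes$x[1], fixes$y[1]),
                cbind(tt_visits$pool_x, tt_visits$pool_y))
    wt <- c(fixes$t[1], tt_visits$t_arrive)
    dup <- c(FALSE, .seg_lengths(wp) == 0)
    TT <- trajectory(fixes[1:i_split, , drop = FALSE], wp[!dup, , drop = FALSE],
                     phase = "TT", waypoint_times = wt[!dup],
                     interpolated_start_m = interp)
  }

  n <- nrow(fixes)
  ht_fix_idx <- i_split:n
  d_home <- sqrt((fixes$x - territory$center[1])^2 +
                 (fixes$y - territory$center[2])^2)
  back <- which(seq_len(n) > i_split & d_home <= r_home)
  complete <- length(back) > 0
  if (complete) ht_fix_idx <- i_split:min(back)
  HT <- NULL
  if (length(ht_fix_idx) >= 2) {
    ht_fixes <- fixes[ht_fix_idx, , drop = FALSE]
    wp <- rbind(c(last_dep$pool_x, last_dep$pool_y),
                unname(territory$center))
    wt <- c(ht_fixes$t[1], ht_fixes$t[nrow(ht_fixes)])
    HT <- trajectory(ht_fixes, wp, phase = "HT", waypoint_times = wt,
                     complete = complete)
  }
  list(TT = TT, HT = HT)
}
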