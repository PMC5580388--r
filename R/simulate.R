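# Seeded generator of landscapes, goal-biased two-state walks and covariate
# series with the statistical structure the analysis pipeline assumes.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study. The defaults emulate the
#' field design the analysis was built for: a cross-shaped array of 13 pools
#' at 20 m spacing with every second pool removed (8 available), territories
#' scattered around the array, stop-and-go goal-directed movement relocated
#' every 30-60 min during a 07:00-19:00 daylight window over multiple days
#' with night gaps, tadpole loads with mean 8.5 (sd 4.9, truncated to 1-25),
#' and a 1.41-fold speed increase while carrying tadpoles.
#'
#' @param seed master RNG seed; every stochastic operation draws from a
#'   named sub-stream derived from it, so identical configs give
#'   bit-identical output.
#' @param n_frogs number of tracked frogs.
#' @param kappa von Mises concentration of the per-minute heading around the
#'   bearing to the current goal (0 = uniform headings).
#' @param p_move per-minute probability of switching pause -> move.
#' @param p_pause per-minute probability of switching move -> pause.
#' @param step_mean_m mean per-minute step length (m) in the move state,
#'   without tadpoles.
#' @param speed_ratio_tt multiplicative speed factor while tadpoles are
#'   carried.
#' @param step_cap_m upper cap on per-minute base steps; keeps observed
#'   fix-to-fix speeds inside the realistic 0-70 m/h range.
#' @param fix_interval_min relocation interval in minutes; `NULL` draws one
#'   value per frog uniformly from 30-60.
#' @param pool_spacing,n_pools cross-array geometry (13 pools, 20 m apart).
#' @param removed_every_second experimentally remove every second pool along
#'   each transect (the centre and the mid-arm ring), leaving 8 available.
#' @param tadpole_mean,tadpole_sd,tadpole_range truncated-normal tadpole
#'   load, rounded to integer.
#' @param day_start,day_end daylight tracking window (clock times).
#' @param r_territory radius (m) used as the returned-home criterion.
#' @param jitter_sd sd (m) of the positional measurement noise on fixes.
#' @param r_goal arrival radius (m) at which a goal counts as reached.
#' @param dwell_extra_min minutes spent at a pool beyond one fix interval,
#'   so every visit is covered by at least one fix.
#' @param dash_min,dash_speed_m short determined departure burst after
#'   leaving a pool (minutes, m/min).
#' @param p_nearest probability that the next itinerary pool is the nearest
#'   available one (otherwise a random reachable pool, which may be a
#'   removed one).
#' @param n_pools_itinerary inclusive range of pools per itinerary.
#' @param clearance_m minimum clearance (m) between a planned between-goal
#'   leg and any third pool, so transit legs do not run over other pools.
#' @param start_date first tracking day.
#' @param max_days simulation cap; exceeding it is an error (unreachable
#'   goal).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_frogs = 16, kappa = 1,
                       p_move = 0.15, p_pause = 0.30,
                       step_mean_m = 0.35, speed_ratio_tt = 1.41,
                       step_cap_m = 1.1, fix_interval_min = NULL,
                       pool_spacing = 20, n_pools = 13,
                       removed_every_second = TRUE,
                       tadpole_mean = 8.5, tadpole_sd = 4.9,
                       tadpole_range = c(1, 25),
                       day_start = "07:00", day_end = "19:00",
                       r_territory = 7, jitter_sd = 0.5, r_goal = 0.5,
                       dwell_extra_min = 10, dash_min = 2, dash_speed_m = 4,
                       p_nearest = 0.7, n_pools_itinerary = c(1, 4),
                       clearance_m = 12, start_date = "2015-02-01",
                       max_days = 12) {
  cfg <- as.list(environment())
  stopifnot(kappa >= 0, p_move >= 0, p_move <= 1, p_pause >= 0, p_pause <= 1,
            step_mean_m > 0, speed_ratio_tt > 0, pool_spacing > 0,
            n_frogs >= 0, jitter_sd >= 0, r_goal > 0,
            tadpole_range[1] >= 1, tadpole_range[2] <= 25)
  if (!is.null(fix_interval_min)) {
    stopifnot(fix_interval_min >= 30, fix_interval_min <= 60)
  }
  cfg$window <- daylight_window(day_start, day_end)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the circular
#' uniform.
#'
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return angles in radians, wrapped to `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- mu + sign(runif(1) - 0.5) * acos(f)
        break
      }
    }
  }
  out %% (2 * pi)
}

# Integer tadpole load from a truncated normal.
.draw_load <- function(cfg) {
  repeat {
    v <- round(rnorm(1, cfg$tadpole_mean, cfg$tadpole_sd))
    if (v >= cfg$tadpole_range[1] && v <= cfg$tadpole_range[2]) return(v)
  }
}

#' Build the synthetic study landscape
#'
#' Thirteen artificial pools in a cross (one centre pool plus three per
#' cardinal arm at `pool_spacing` intervals). With
#' `removed_every_second = TRUE` every second pool along each transect (the
#' centre and the four mid-arm pools) is flagged removed, leaving 8
#' available. Territory centres are drawn uniformly in an annulus 10-60 m
#' from the array centre, at least 5 m from any pool.
#'
#' @param cfg a [sim_config()].
#' @return list with `pools` (a `frog_pools` data frame) and `territories`
#'   (`frog_id`, `x`, `y`).
#' @export
build_landscape <- function(cfg) {
  s <- cfg$pool_spacing
  # UTM-like offset so synthetic coordinates look like (and validate as)
  # projected planar metres, not longitude/latitude
  origin <- c(313000, 441000)
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  xy <- rbind(c(0, 0),
              do.call(rbind, lapply(1:3, function(ring)
                dirs * ring * s)))
  xy <- sweep(xy, 2, origin, "+")
  ring <- c(0, rep(1:3, each = 4))
  removed <- if (isTRUE(cfg$removed_every_second)) ring %% 2 == 0 else
    rep(FALSE, nrow(xy))
  pools <- data.frame(
    pool_id = sprintf("P%02d", seq_len(nrow(xy))),
    x = xy[, 1], y = xy[, 2],
    kind = "artificial",
    status = ifelse(removed, "removed", "available"),
    stringsAsFactors = FALSE
  )
  class(pools) <- c("frog_pools", "data.frame")
  territories <- with_substream(cfg$seed, "landscape", {
    if (cfg$n_frogs == 0) {
      data.frame(frog_id = character(0), x = numeric(0), y = numeric(0))
    } else {
      pts <- matrix(NA_real_, cfg$n_frogs, 2)
      for (i in seq_len(cfg$n_frogs)) {
        repeat {
          rr <- sqrt(runif(1, 10^2, 60^2))
          th <- runif(1, 0, 2 * pi)
          p <- origin + c(rr * cos(th), rr * sin(th))
          if (min(sqrt((pools$x - p[1])^2 + (pools$y - p[2])^2)) >= 5) {
            pts[i, ] <- p
            break
          }
        }
      }
      data.frame(frog_id = sprintf("F%02d", seq_len(cfg$n_frogs)),
                 x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
    }
  })
  list(pools = pools, territories = territories)
}

# Minimum distance from segment a-b to any pool other than `exclude`.
.seg_clearance <- function(a, b, pools, exclude = character(0)) {
  others <- which(!pools$pool_id %in% exclude)
  if (!length(others)) return(Inf)
  min(vapply(others, function(i) {
    .point_line_dist(c(pools$x[i], pools$y[i]), a, b, clamp = TRUE)
  }, numeric(1)))
}

# Plan an itinerary of 1-4 pools: nearest-available-first with probability
# p_nearest, otherwise a random reachable pool (possibly removed); legs must
# clear third pools by clearance_m; the final pool is always available.
.plan_itinerary <- function(cfg, pools, start) {
  k_target <- sample(seq(cfg$n_pools_itinerary[1], cfg$n_pools_itinerary[2]), 1)
  chosen <- character(0)
  cur <- start
  while (length(chosen) < k_target) {
    open <- pools[!pools$pool_id %in% chosen, , drop = FALSE]
    d <- sqrt((open$x - cur[1])^2 + (open$y - cur[2])^2)
    clear <- vapply(seq_len(nrow(open)), function(i) {
      .seg_clearance(cur, c(open$x[i], open$y[i]), pools,
                     exclude = c(chosen, open$pool_id[i])) > cfg$clearance_m
    }, logical(1))
    cand <- open[clear, , drop = FALSE]
    dc <- d[clear]
    if (!nrow(cand)) break
    avail <- cand$status == "available"
    pick <- if (runif(1) < cfg$p_nearest && any(avail)) {
      cand$pool_id[avail][which.min(dc[avail])]
    } else {
      cand$pool_id[sample.int(nrow(cand), 1)]
    }
    chosen <- c(chosen, pick)
    i <- match(pick, pools$pool_id)
    cur <- c(pools$x[i], pools$y[i])
  }
  if (!length(chosen)) {
    # degenerate geometry: fall back to the nearest available pool
    open <- pools[pools$status == "available", , drop = FALSE]
    d <- sqrt((open$x - start[1])^2 + (open$y - start[2])^2)
    chosen <- open$pool_id[which.min(d)]
    i <- match(chosen, pools$pool_id)
    cur <- c(pools$x[i], pools$y[i])
  }
  last <- chosen[length(chosen)]
  if (pools$status[match(last, pools$pool_id)] != "available") {
    open <- pools[pools$status == "available" &
                    !pools$pool_id %in% chosen, , drop = FALSE]
    d <- sqrt((open$x - cur[1])^2 + (open$y - cur[2])^2)
    clear <- vapply(seq_len(nrow(open)), function(i) {
      .seg_clearance(cur, c(open$x[i], open$y[i]), pools,
                     exclude = c(chosen, open$pool_id[i])) > cfg$clearance_m
    }, logical(1))
    pick <- if (any(clear)) open$pool_id[clear][which.min(d[clear])] else
      open$pool_id[which.min(d)]
    chosen <- c(chosen, pick)
  }
  chosen
}

# Advance a clock time by one minute, skipping the night.
.next_active_min <- function(t, window) {
  t <- t + 60
  if (.min_of_day(t) > window$end_min) {
    d <- as.Date(t, tz = "UTC") + 1
    t <- as.POSIXct(paste(d, sprintf("%02d:%02d:00", window$start_min %/% 60,
                                     window$start_min %% 60)), tz = "UTC")
  }
  t
}

#' Simulate one tadpole transport and homing track
#'
#' Two-state (move/pause) goal-biased random walk at one-minute resolution:
#' in the move state the heading is von Mises around the bearing to the
#' current goal and the step length is (capped) exponential, scaled by
#' `speed_ratio_tt` while tadpoles are carried. The frog follows its planned
#' pool itinerary (deposits split across the available pools, none at
#' removed ones), dwells at each pool long enough to be covered by a fix,
#' then returns to its territory. Fixes subsample the walk at the frog's
#' relocation interval inside the daylight window (nights skipped), starting
#' from a random encounter point part-way to the first pool, with Gaussian
#' positional noise.
#'
#' @param cfg a [sim_config()].
#' @param landscape a [build_landscape()] result.
#' @param frog_id which territory/frog to simulate.
#' @return list with `fixes` (a `frog_fixes` data frame) and `truth`: the
#'   itinerary (pool ids, status, deposits), initial load, per-fix phase
#'   (TT/HT) and movement-state labels, the true pre-encounter path length,
#'   the split fix index, and the generating parameters.
#' @export
simulate_transport <- function(cfg, landscape, frog_id) {
  terr <- landscape$territories[landscape$territories$frog_id == frog_id, ]
  if (nrow(terr) != 1) stop("unknown frog_id: ", frog_id, call. = FALSE)
  pools <- landscape$pools
  with_substream(cfg$seed, paste0("transport-", frog_id), {
    fix_int <- cfg$fix_interval_min %||% sample(30:60, 1)
    load <- .draw_load(cfg)
    itinerary <- .plan_itinerary(cfg, pools, c(terr$x, terr$y))
    it_idx <- match(itinerary, pools$pool_id)
    it_status <- pools$status[it_idx]
    avail <- which(it_status == "available")
    dep <- integer(length(itinerary))
    base <- load %/% length(avail)
    dep[avail] <- base
    dep[avail[length(avail)]] <- base + load %% length(avail)
    goals <- rbind(cbind(pools$x[it_idx], pools$y[it_idx]),
                   c(terr$x, terr$y))
    dwell_len <- fix_int + cfg$dwell_extra_min

    nmax <- cfg$max_days * (cfg$window$end_min - cfg$window$start_min)
    T_ <- numeric(nmax); X <- numeric(nmax); Y <- numeric(nmax)
    TAD <- integer(nmax); MODE <- character(nmax); PHASE <- character(nmax)

    t <- as.POSIXct(paste(cfg$start_date, "07:00:00"), tz = "UTC") +
      round(runif(1, 0, 180)) * 60
    pos <- c(terr$x, terr$y)
    tad <- load
    mode <- "move"           # move / pause / dwell / dash / settle
    phase <- "TT"
    gi <- 1L                 # current goal index into `goals`
    dwell_left <- 0L; dash_left <- 0L; settle_left <- -1L
    arrive_row <- rep(NA_integer_, length(itinerary))
    i <- 0L
    repeat {
      i <- i + 1L
      if (i > nmax) stop("goal unreachable within max_days", call. = FALSE)
      T_[i] <- as.numeric(t); X[i] <- pos[1]; Y[i] <- pos[2]
      TAD[i] <- tad; MODE[i] <- mode; PHASE[i] <- phase
      if (mode == "settle") {
        if (settle_left <= 0L) break
        settle_left <- settle_left - 1L
      } else if (mode == "dwell") {
        dwell_left <- dwell_left - 1L
        if (dwell_left <= 0L) {
          if (gi == length(itinerary)) phase <- "HT"
          gi <- gi + 1L
          mode <- "dash"
          dash_left <- cfg$dash_min
        }
      } else {
        goal <- goals[min(gi, nrow(goals)), ]
        if (mode == "dash") {
          step <- cfg$dash_speed_m
          dash_left <- dash_left - 1L
          if (dash_left <= 0L) mode <- "move"
          heading <- atan2(goal[2] - pos[2], goal[1] - pos[1])
        } else {
          if (mode == "move" && runif(1) < cfg$p_pause) mode <- "pause"
          else if (mode == "pause" && runif(1) < cfg$p_move) mode <- "move"
          if (mode == "move") {
            heading <- rvonmises(1, atan2(goal[2] - pos[2], goal[1] - pos[1]),
                                 cfg$kappa)
            step <- min(rexp(1, 1 / cfg$step_mean_m), cfg$step_cap_m) *
              (if (tad > 0) cfg$speed_ratio_tt else 1)
          } else step <- 0
        }
        if (step > 0) {
          d_goal <- .dist2(pos, goal)
          if (d_goal <= max(step, cfg$r_goal)) {
            pos <- goal
            if (gi <= length(itinerary)) {
              arrive_row[gi] <- i + 1L
              tad <- tad - dep[gi]
              mode <- "dwell"
              dwell_left <- dwell_len
            } else {
              mode <- "settle"
              settle_left <- dwell_len
            }
          } else {
            pos <- pos + step * c(cos(heading), sin(heading))
          }
        }
      }
      t <- .next_active_min(t, cfg$window)
    }
    n <- i
    walk <- data.frame(t = as.POSIXct(T_[1:n], origin = "1970-01-01",
                                      tz = "UTC"),
                       x = X[1:n], y = Y[1:n], tadpoles = TAD[1:n],
                       mode = MODE[1:n], phase = PHASE[1:n],
                       stringsAsFactors = FALSE)
    # phase labels follow position: the transport phase runs through the
    # last minute actually spent at the final deposition pool (rows record
    # the position at the start of each minute, so the first post-dwell row
    # still sits on the pool)
    fp <- goals[length(itinerary), ]
    at_fp <- which(walk$x == fp[1] & walk$y == fp[2])
    walk$phase <- ifelse(seq_len(n) <= max(at_fp), "TT", "HT")
    cum <- c(0, cumsum(.seg_lengths(cbind(walk$x, walk$y))))
    a1 <- arrive_row[1]
    enc <- max(1L, floor(runif(1, 0.2, 0.6) * (a1 - fix_int - 2)))
    fix_rows <- seq(enc, n, by = fix_int)
    if (fix_rows[length(fix_rows)] != n) fix_rows <- c(fix_rows, n)
    fixes <- data.frame(
      frog_id = frog_id,
      t = walk$t[fix_rows],
      x = walk$x[fix_rows] + rnorm(length(fix_rows), 0, cfg$jitter_sd),
      y = walk$y[fix_rows] + rnorm(length(fix_rows), 0, cfg$jitter_sd),
      tadpoles = walk$tadpoles[fix_rows],
      behavior = ifelse(walk$tadpoles[fix_rows] > 0, "transport", "other"),
      stringsAsFactors = FALSE
    )
    class(fixes) <- c("frog_fixes", "data.frame")
    truth <- list(
      frog_id = frog_id,
      itinerary = data.frame(pool_id = itinerary, status = it_status,
                             deposit = dep, stringsAsFactors = FALSE),
      load = load,
      territory = c(x = terr$x, y = terr$y),
      fix_phase = walk$phase[fix_rows],
      fix_state = walk$mode[fix_rows],
      split_fix = max(which(walk$phase[fix_rows] == "TT")),
      pre_encounter_path_m = cum[enc],
      encounter_row = enc,
      fix_interval = fix_int,
      kappa = cfg$kappa, speed_ratio_tt = cfg$speed_ratio_tt
    )
    list(fixes = fixes, truth = truth)
  })
}

#' Simulate a full synthetic tracking study
#'
#' Builds the landscape, simulates one transport + homing track per frog,
#' and generates a capture table around each territory centre (mostly
#' territorial-behaviour captures, from which the analysis re-derives the
#' centres).
#'
#' @param cfg a [sim_config()].
#' @return a `sim_study` list: `config`, `landscape`, `fixes` (all frogs),
#'   `captures`, and per-frog `truth`.
#' @export
simulate_study <- function(cfg) {
  landscape <- build_landscape(cfg)
  runs <- lapply(landscape$territories$frog_id, function(id) {
    simulate_transport(cfg, landscape, id)
  })
  fixes <- do.call(rbind, lapply(runs, `[[`, "fixes"))
  if (is.null(fixes)) {
    fixes <- data.frame(frog_id = character(0), t = as.POSIXct(character(0)),
                        x = numeric(0), y = numeric(0),
                        tadpoles = integer(0), behavior = character(0))
    class(fixes) <- c("frog_fixes", "data.frame")
  }
  captures <- with_substream(cfg$seed, "captures", {
    if (nrow(landscape$territories) == 0) {
      data.frame(frog_id = character(0), t = as.POSIXct(character(0)),
                 x = numeric(0), y = numeric(0), territorial = logical(0))
    } else
    do.call(rbind, lapply(seq_len(nrow(landscape$territories)), function(i) {
      tr <- landscape$territories[i, ]
      n_t <- sample(8:20, 1)
      n_o <- sample(0:4, 1)
      data.frame(
        frog_id = tr$frog_id,
        t = as.POSIXct(paste(cfg$start_date, "08:00:00"), tz = "UTC") -
          sample(1:30, n_t + n_o, replace = TRUE) * 86400,
        x = c(rnorm(n_t, tr$x, 2), rnorm(n_o, tr$x, 8)),
        y = c(rnorm(n_t, tr$y, 2), rnorm(n_o, tr$y, 8)),
        territorial = rep(c(TRUE, FALSE), c(n_t, n_o)),
        stringsAsFactors = FALSE
      )
    }))
  })
  structure(list(config = cfg, landscape = landscape, fixes = fixes,
                 captures = captures,
                 truth = setNames(lapply(runs, `[[`, "truth"),
                                  landscape$territories$frog_id)),
            class = "sim_study")
}

#' Simulate a weather covariate series
#'
#' Per-3-hour-interval (07-10, 10-13, 13-16, 16-19 h) above-canopy
#' temperature (sinusoidal daily cycle plus Gaussian noise) and cumulative
#' rainfall (zero-inflated gamma).
#'
#' @param cfg a [sim_config()] (source of the seed and day window).
#' @param n_days number of days.
#' @param temp_mean,temp_amp,temp_noise_sd temperature cycle parameters
#'   (deg C); the cycle peaks mid-afternoon.
#' @param rain_p per-interval probability of any rain.
#' @param rain_shape,rain_mean gamma parameters of nonzero rainfall (mm).
#' @return data frame `day`, `interval` (1-4), `mid_hour`, `temp`, `rain`.
#' @export
simulate_covariates <- function(cfg, n_days = 30, temp_mean = 26,
                                temp_amp = 4, temp_noise_sd = 1,
                                rain_p = 0.3, rain_shape = 1.5,
                                rain_mean = 6) {
  with_substream(cfg$seed, "covariates", {
    grid <- expand.grid(interval = 1:4, day = seq_len(n_days))
    grid$mid_hour <- 7 + (grid$interval - 1) * 3 + 1.5
    n <- nrow(grid)
    grid$temp <- temp_mean +
      temp_amp * sin(2 * pi * (grid$mid_hour - 9) / 24) +
      rnorm(n, 0, temp_noise_sd)
    wet <- rbinom(n, 1, rain_p)
    grid$rain <- wet * rgamma(n, shape = rain_shape,
                              scale = rain_mean / rain_shape)
    grid[, c("day", "interval", "mid_hour", "temp", "rain")]
  })
}

#' Simulate per-interval movement speeds with configurable covariate effects
#'
#' Generates a gamma-distributed speed observation per frog and 3 h interval
#' whose log mean responds linearly to tadpole presence and to the
#' (standardised) weather covariates — the data layout of the
#' speed-versus-weather analysis, used to verify that the all-subset model
#' selection recovers effects that are present and stays with the null when
#' they are not.
#'
#' @param covariates a [simulate_covariates()] table.
#' @param n_frogs frogs per interval.
#' @param base_speed median speed (m/h) with no tadpoles at average weather.
#' @param beta_tad,beta_temp,beta_rain log-scale effect sizes.
#' @param shape gamma shape (inverse squared coefficient of variation).
#' @param seed RNG seed.
#' @return data frame `frog_id`, `day`, `interval`, `tadpoles_present`,
#'   `temp_z`, `rain_z`, `speed`.
#' @export
simulate_interval_speeds <- function(covariates, n_frogs = 16,
                                     base_speed = 7.22, beta_tad = 0.34,
                                     beta_temp = 0, beta_rain = 0,
                                     shape = 5, seed = 1) {
  with_substream(seed, "interval-speeds", {
    rows <- covariates[rep(seq_len(nrow(covariates)), each = n_frogs), ]
    rows$frog_id <- rep(sprintf("F%02d", seq_len(n_frogs)),
                        times = nrow(covariates))
    rows$tadpoles_present <- rbinom(nrow(rows), 1,
                                    ifelse(rows$interval == 1, 0.6, 0.2))
    rows$temp_z <- as.numeric(scale(rows$temp))
    rows$rain_z <- as.numeric(scale(rows$rain))
    mu <- base_speed * exp(beta_tad * rows$tadpoles_present +
                             beta_temp * rows$temp_z +
                             beta_rain * rows$rain_z)
    rows$speed <- rgamma(nrow(rows), shape = shape, scale = mu / shape)
    rownames(rows) <- NULL
    rows[, c("frog_id", "day", "interval", "tadpoles_present",
             "temp_z", "rain_z", "speed")]
  })
}

#' Simulate per-trajectory mean speeds for the tadpole-effect contrast
#'
#' One transport (with tadpoles) and one homing (without) mean speed per
#' frog, gamma-distributed around the two phase means — the observation
#' layout of the speed-versus-tadpole-presence mixed model.
#'
#' @param n_frogs number of frogs (two observations each).
#' @param mean_tt,mean_ht phase mean speeds (m/h).
#' @param shape gamma shape parameter.
#' @param seed RNG seed.
#' @return data frame `frog_id`, `tadpoles_present` (1 = transport),
#'   `speed`.
#' @export
simulate_speed_data <- function(n_frogs = 16, mean_tt = 10.16,
                                mean_ht = 7.22, shape = 5, seed = 1) {
  with_substream(seed, "speed-data", {
    d <- data.frame(
      frog_id = rep(sprintf("F%02d", seq_len(n_frogs)), 2),
      tadpoles_present = rep(c(1, 0), each = n_frogs),
      stringsAsFactors = FALSE
    )
    mu <- ifelse(d$tadpoles_present == 1, mean_tt, mean_ht)
    d$speed <- rgamma(nrow(d), shape = shape, scale = mu / shape)
    d
  })
}
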