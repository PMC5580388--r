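# Shared fixtures and independent brute-force oracles.

T0 <- as.POSIXct("2015-02-01 08:00:00", tz = "UTC")

# Build a minimal fixes data frame from coordinates at fixed intervals.
make_fixes <- function(x, y, t = T0 + (seq_along(x) - 1) * 1800,
                       frog_id = "F01", tadpoles = NA_integer_,
                       behavior = "unknown") {
  data.frame(frog_id = frog_id, t = t, x = x, y = y,
             tadpoles = tadpoles, behavior = behavior,
             stringsAsFactors = FALSE)
}

make_traj <- function(x, y, waypoints, phase = "TT",
                      t = T0 + (seq_along(x) - 1) * 1800, ...) {
  trajectory(make_fixes(x, y, t = t), waypoints, phase = phase, ...)
}

# --- independent oracles (deliberately naive implementations) ------------

# Path length by explicit pairwise summation.
bf_path_length <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  s
}

# Point-to-infinite-line distance via the classic coefficient formula.
bf_point_line <- function(px, py, x1, y1, x2, y2) {
  a <- y2 - y1; b <- -(x2 - x1); cc <- -(a * x1 + b * y1)
  abs(a * px + b * py + cc) / sqrt(a^2 + b^2)
}

# Night-excluded duration by summing daylight overlap day by day.
bf_active_hours <- function(t0, t1, start_h = 7, end_h = 19) {
  days <- seq(as.Date(t0, tz = "UTC"), as.Date(t1, tz = "UTC"), by = "day")
  tot <- 0
  for (d in days) {
    d <- as.Date(d, origin = "1970-01-01")
    w0 <- as.POSIXct(paste(d, sprintf("%02d:00:00", start_h)), tz = "UTC")
    w1 <- as.POSIXct(paste(d, sprintf("%02d:00:00", end_h)), tz = "UTC")
    lo <- max(as.numeric(w0), as.numeric(t0))
    hi <- min(as.numeric(w1), as.numeric(t1))
    if (hi > lo) tot <- tot + (hi - lo) / 3600
  }
  tot
}

# Straightness coefficient with fix-anchored chord, recomputed naively.
bf_sc <- function(x, y, wx, wy) {
  n <- length(x)
  vid <- 1
  if (length(wx) > 2) {
    for (j in 2:(length(wx) - 1)) {
      cand <- setdiff(seq_len(n - 1), seq_len(vid[length(vid)]))
      if (!length(cand)) next
      dd <- sqrt((x[cand] - wx[j])^2 + (y[cand] - wy[j])^2)
      vid <- c(vid, cand[which.min(dd)])
    }
  }
  vid <- c(vid, n)
  num <- 0
  for (k in 2:length(vid)) {
    num <- num + sqrt((x[vid[k]] - x[vid[k - 1]])^2 +
                        (y[vid[k]] - y[vid[k - 1]])^2)
  }
  num / bf_path_length(x, y)
}

# Mean absolute angular deviation towards a single fixed goal.
bf_ang_dev <- function(x, y, gx, gy) {
  n <- length(x)
  vals <- c()
  for (i in 1:(n - 1)) {
    if (x[i] == x[i + 1] && y[i] == y[i + 1]) next
    ideal <- atan2(gy - y[i], gx - x[i])
    act <- atan2(y[i + 1] - y[i], x[i + 1] - x[i])
    d <- (act - ideal) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    vals <- c(vals, abs(d) * 180 / pi)
  }
  mean(vals)
}

# Monte-Carlo null for the Rayleigh p-value.
mc_rayleigh_p <- function(angles_deg, reps = 20000) {
  n <- length(angles_deg)
  a <- angles_deg * pi / 180
  robs <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  th <- matrix(runif(n * reps, 0, 2 * pi), nrow = n)
  rnull <- sqrt(colMeans(cos(th))^2 + colMeans(sin(th))^2)
  mean(rnull >= robs)
}

# Quick single-frog synthetic run analysed with the pipeline pieces.
sim_one <- function(seed, kappa = NULL, ...) {
  args <- list(seed = seed, n_frogs = 1, ...)
  if (!is.null(kappa)) args$kappa <- kappa
  cfg <- do.call(sim_config, args)
  ls <- build_landscape(cfg)
  r <- simulate_transport(cfg, ls, "F01")
  terr <- territory_center(cbind(r$truth$territory[["x"]],
                                 r$truth$territory[["y"]]),
                           frog_id = "F01")
  v <- suppressWarnings(detect_visits(r$fixes, ls$pools, r_visit = 2.5))
  v <- infer_depositions(v, r$fixes)
  seg <- segment_phases(r$fixes, v, terr)
  list(cfg = cfg, landscape = ls, run = r, territory = terr,
       visits = v, seg = seg)
}
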