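# Deposition-site (pool) tables, visit detection and deposition inference.

.pool_status_levels <- c("available", "removed", "dry")

#' Read a pool-site table
#'
#' Pool CSV dialect: `pool_id`, `x_m`, `y_m`, `kind`
#' (artificial/natural) and availability either as a single `status` column
#' (constant over the study) or as status windows with columns `status`,
#' `t_from`, `t_to` (one row per pool and window; empty bounds are open).
#'
#' @param path path to the pool CSV.
#' @param delim field delimiter, default comma.
#' @return a `frog_pools` data frame (`pool_id`, `x`, `y`, `kind`, `status`)
#'   with any status windows in `attr(, "windows")`.
#' @export
read_pools <- function(path, delim = ",") {
  raw <- read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (need in c("pool_id", "x_m", "y_m", "status")) {
    if (!need %in% names(raw)) {
      stop(sprintf("missing required column '%s' in pool table", need),
           call. = FALSE)
    }
  }
  if (!all(raw$status %in% .pool_status_levels)) {
    stop("pool status must be one of: ",
         paste(.pool_status_levels, collapse = ", "), call. = FALSE)
  }
  windows <- NULL
  if (all(c("t_from", "t_to") %in% names(raw))) {
    windows <- data.frame(pool_id = as.character(raw$pool_id),
                          status = raw$status,
                          t_from = .parse_time(raw$t_from),
                          t_to = .parse_time(raw$t_to),
                          stringsAsFactors = FALSE)
  }
  first <- !duplicated(raw$pool_id)
  pools <- data.frame(
    pool_id = as.character(raw$pool_id[first]),
    x = as.numeric(raw$x_m[first]), y = as.numeric(raw$y_m[first]),
    kind = if ("kind" %in% names(raw)) as.character(raw$kind[first])
           else "artificial",
    status = raw$status[first],
    stringsAsFactors = FALSE
  )
  attr(pools, "windows") <- windows
  class(pools) <- c("frog_pools", "data.frame")
  pools
}

#' Availability status of a pool at a given time
#'
#' @param pools a `frog_pools` data frame.
#' @param pool_id pool identifier.
#' @param t POSIXct query time; only used when the pool table carries status
#'   windows.
#' @return `"available"`, `"removed"` or `"dry"`.
#' @export
pool_status <- function(pools, pool_id, t = NULL) {
  i <- match(pool_id, pools$pool_id)
  if (is.na(i)) stop("unknown pool_id: ", pool_id, call. = FALSE)
  w <- attr(pools, "windows")
  if (is.null(w) || is.null(t)) return(pools$status[i])
  w <- w[w$pool_id == pool_id, , drop = FALSE]
  hit <- (is.na(w$t_from) | w$t_from <= t) & (is.na(w$t_to) | t <= w$t_to)
  if (!any(hit)) {
    stop(sprintf("status of pool %s undefined at %s", pool_id, format(t)),
         call. = FALSE)
  }
  w$status[which(hit)[1]]
}

#' Detect pool visits along a track
#'
#' A visit is a maximal run of consecutive fixes within `r_visit` metres of a
#' pool centre (the nearest pool wins where radii overlap). Two runs at the
#' same pool separated by a single out-of-radius fix spanning less than
#' `merge_gap_min` minutes are merged into one event (tracking noise).
#'
#' @param traj a `frog_trajectory` or a fixes data frame for one frog.
#' @param pools a `frog_pools` data frame.
#' @param r_visit visit radius in metres (default 1 m); the field definition
#'   of a visit is the frog actually entering the site, so the radius is a
#'   positional proxy and should be set relative to the fix measurement
#'   noise.
#' @param merge_gap_min gap-merging threshold in minutes.
#' @return a `frog_visits` data frame: `frog_id`, `pool_id`, `pool_x`,
#'   `pool_y`, `t_arrive`, `t_depart`, `n_fixes`, `status_at_visit`, and
#'   placeholder columns `deposition`, `tadpoles_before`, `tadpoles_after`
#'   (`NA` until [infer_depositions()] fills them), ordered by arrival time.
#' @export
detect_visits <- function(traj, pools, r_visit = 1, merge_gap_min = 30) {
  fixes <- if (inherits(traj, "frog_trajectory")) traj$fixes else traj
  stopifnot(nrow(pools) >= 1, r_visit > 0)
  if (nrow(pools) > 1) {
    dmin <- min(dist(cbind(pools$x, pools$y)))
    if (dmin < 2 * r_visit) {
      warning("pools closer than 2 * r_visit: visit assignment may be ambiguous")
    }
  }
  dx <- outer(fixes$x, pools$x, "-")
  dy <- outer(fixes$y, pools$y, "-")
  dd <- sqrt(dx^2 + dy^2)
  nearest <- apply(dd, 1, which.min)
  ndist <- dd[cbind(seq_len(nrow(fixes)), nearest)]
  inside <- ndist <= r_visit
  key <- ifelse(inside, nearest, 0L)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(pool_idx = r$values, i0 = starts, i1 = ends)
  ev <- ev[ev$pool_idx > 0, , drop = FALSE]
  # merge events at the same pool separated by one short out-of-radius fix
  if (nrow(ev) >= 2) {
    keep <- rep(TRUE, nrow(ev))
    for (k in 2:nrow(ev)) {
      prev <- max(which(keep[1:(k - 1)]))
      gap_fixes <- ev$i0[k] - ev$i1[prev] - 1L
      gap_min <- as.numeric(difftime(fixes$t[ev$i0[k]], fixes$t[ev$i1[prev]],
                                     units = "mins"))
      if (ev$pool_idx[k] == ev$pool_idx[prev] && gap_fixes == 1L &&
          gap_min < merge_gap_min) {
        ev$i1[prev] <- ev$i1[k]
        keep[k] <- FALSE
      }
    }
    ev <- ev[keep, , drop = FALSE]
  }
  out <- data.frame(
    frog_id = if (nrow(ev)) fixes$frog_id[ev$i0] else character(0),
    pool_id = pools$pool_id[ev$pool_idx],
    pool_x = pools$x[ev$pool_idx], pool_y = pools$y[ev$pool_idx],
    t_arrive = fixes$t[ev$i0], t_depart = fixes$t[ev$i1],
    n_fixes = ev$i1 - ev$i0 + 1L,
    stringsAsFactors = FALSE
  )
  out$status_at_visit <- vapply(seq_len(nrow(out)), function(k) {
    pool_status(pools, out$pool_id[k], out$t_arrive[k])
  }, character(1))
  out$deposition <- rep(NA, nrow(out))
  out$tadpoles_before <- rep(NA_integer_, nrow(out))
  out$tadpoles_after <- rep(NA_integer_, nrow(out))
  out <- out[order(out$t_arrive), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frog_visits", "data.frame")
  out
}

#' Infer tadpole depositions from counts across visits
#'
#' A deposition is inferred when the pool was available at the visit and the
#' tadpole count strictly drops across the visit. Because the count can
#' never increase, the pre-visit load is taken as the largest known count
#' from the last fix before arrival through the end of the visit, and the
#' post-visit count as the first known count at or after the last in-visit
#' fix. Unknown counts leave the deposition flag `NA` — never guessed. A
#' count that increases across a visit is a validation error (tadpoles
#' cannot be gained).
#'
#' @param visits a `frog_visits` data frame.
#' @param fixes the fixes data frame the visits were detected on (source of
#'   the tadpole counts).
#' @return `visits` with `tadpoles_before`, `tadpoles_after`, `deposition`
#'   and `n_deposited` filled in.
#' @export
infer_depositions <- function(visits, fixes) {
  known <- which(!is.na(fixes$tadpoles))
  for (k in seq_len(nrow(visits))) {
    # the count can never increase, so the pre-visit load is the largest
    # known count from the last fix before arrival through the end of the
    # visit (a slow approach can put the last pre-deposition fix inside
    # the visit radius)
    before_i <- known[fixes$t[known] < visits$t_arrive[k]]
    within_i <- known[fixes$t[known] >= visits$t_arrive[k] &
                        fixes$t[known] <= visits$t_depart[k]]
    after_i <- known[fixes$t[known] >= visits$t_depart[k]]
    cand <- c(if (length(before_i)) fixes$tadpoles[max(before_i)],
              fixes$tadpoles[within_i])
    before <- if (length(cand)) max(cand) else NA_integer_
    after <- if (length(after_i)) fixes$tadpoles[min(after_i)] else NA_integer_
    run <- c(cand, after)
    if (length(run) > 1 && any(diff(run) > 0)) {
      stop(sprintf("tadpole count increases across visit to pool %s",
                   visits$pool_id[k]), call. = FALSE)
    }
    visits$tadpoles_before[k] <- before
    visits$tadpoles_after[k] <- after
    if (!is.na(before) && !is.na(after)) {
      if (after > before) {
        stop(sprintf("tadpole count increases across visit to pool %s (%d -> %d)",
                     visits$pool_id[k], before, after), call. = FALSE)
      }
      visits$deposition[k] <- (after < before) &&
        visits$status_at_visit[k] == "available"
    }
  }
  visits$n_deposited <- ifelse(!is.na(visits$deposition) & visits$deposition,
                               visits$tadpoles_before - visits$tadpoles_after,
                               0L)
  visits
}

#' Deposition-site visits per transport event
#'
#' Mean, range and available/non-available breakdown of the distinct
#' deposition sites visited per tadpole transport. Transports with only one
#' final deposition site and no detailed transport track should be excluded
#' by the caller before summarising.
#'
#' @param visit_list a list of `frog_visits` data frames, one per transport
#'   (visits during the TT phase only).
#' @return list with `n_transports`, `mean`, `range`, `per_transport`
#'   (data frame of distinct available / non-available site counts) and the
#'   totals `n_available`, `n_nonavailable`.
#' @export
visits_per_transport <- function(visit_list) {
  if (length(visit_list) == 0) stop("no transports supplied", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(visit_list), function(k) {
    v <- visit_list[[k]]
    first <- !duplicated(v$pool_id)
    avail <- v$status_at_visit[first] == "available"
    data.frame(transport = k, n_sites = sum(first),
               n_available = sum(avail), n_nonavailable = sum(!avail))
  }))
  list(n_transports = nrow(per),
       mean = mean(per$n_sites),
       range = range(per$n_sites),
       per_transport = per,
       n_available = sum(per$n_available),
       n_nonavailable = sum(per$n_nonavailable))
}

#' Post-deposition exploration check
#'
#' Flags, per frog, whether any pool visit happened after the frog had
#' deposited all its tadpoles (tadpoles before the visit = 0) — the
#' operational definition of exploratory pool visiting.
#'
#' @param visits a `frog_visits` data frame (possibly several frogs).
#' @return named logical vector, one element per frog.
#' @export
exploration_check <- function(visits) {
  vapply(split(visits, visits$frog_id), function(v) {
    any(!is.na(v$tadpoles_before) & v$tadpoles_before == 0)
  }, logical(1))
}
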