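# End-to-end runners: write synthetic fixture bundles, analyse a tracking
# data set, and produce the summary tables.

#' Write a synthetic fixture bundle
#'
#' Simulates a full study and writes it in the same CSV dialects the
#' analysis reads — `fixes.csv`, `pools.csv`, `captures.csv` — plus
#' `truth.json` (per-frog ground truth) and `manifest.json` (seed and full
#' parameter echo).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory, created if missing.
#' @return (invisibly) the list of written paths.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(cfg)
  paths <- list(
    fixes = file.path(out_dir, "fixes.csv"),
    pools = file.path(out_dir, "pools.csv"),
    captures = file.path(out_dir, "captures.csv"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_fixes(study$fixes, paths$fixes)
  pools_out <- data.frame(pool_id = study$landscape$pools$pool_id,
                          x_m = study$landscape$pools$x,
                          y_m = study$landscape$pools$y,
                          kind = study$landscape$pools$kind,
                          status = study$landscape$pools$status)
  write.table(pools_out, paths$pools, sep = ",", row.names = FALSE,
              quote = FALSE)
  cap_out <- data.frame(frog_id = study$captures$frog_id,
                        timestamp = .format_time(study$captures$t),
                        x_m = study$captures$x, y_m = study$captures$y,
                        territorial = as.integer(study$captures$territorial))
  write.table(cap_out, paths$captures, sep = ",", row.names = FALSE,
              quote = FALSE)
  truth <- lapply(study$truth, function(tr) {
    tr$fix_phase <- unname(tr$fix_phase); tr$fix_state <- unname(tr$fix_state)
    tr
  })
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  cfg_echo <- cfg[setdiff(names(cfg), "window")]
  jsonlite::write_json(list(seed = cfg$seed, config = cfg_echo),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Analyse one frog's track: visits, depositions, segmentation, summaries.
.analyze_frog <- function(fixes, pools, territory, r_visit, r_home,
                          merge_gap_min, window, min_locations) {
  visits <- detect_visits(fixes, pools, r_visit = r_visit,
                          merge_gap_min = merge_gap_min)
  visits <- infer_depositions(visits, fixes)
  if (!any(!is.na(visits$deposition) & visits$deposition)) {
    return(NULL)   # no recorded deposition: transport incomplete
  }
  seg <- segment_phases(fixes, visits, territory, r_home = r_home)
  split_t <- if (!is.null(seg$TT)) max(seg$TT$fixes$t) else
    seg$HT$fixes$t[1]
  tt_visits <- visits[visits$t_arrive <= split_t, , drop = FALSE]
  list(visits = visits, tt_visits = tt_visits, seg = seg,
       territory = territory)
}

# One TT summary row in the layout of the per-transport results table.
.tt_summary_row <- function(frog_id, tt, tt_visits, window) {
  n_tad <- suppressWarnings(max(tt$fixes$tadpoles, na.rm = TRUE))
  if (!is.finite(n_tad)) n_tad <- NA_integer_
  first <- !duplicated(tt_visits$pool_id)
  avail <- tt_visits$status_at_visit[first] == "available"
  tracked <- path_length(tt)
  chords <- sum(.seg_lengths(tt$waypoints))
  data.frame(
    frog_id = frog_id, n_tadpoles = n_tad,
    tracked_distance_m = tracked,
    total_time_h = active_duration(tt, window),
    avg_speed_mh = mean_speed(tt, window),
    n_sites_visited = sum(first),
    n_sites_available = sum(avail), n_sites_nonavailable = sum(!avail),
    interpolated_start_m = tt$interpolated_start_m,
    total_distance_m = tracked + tt$interpolated_start_m,
    straight_line_m = chords + tt$interpolated_start_m,
    sc = straightness_coefficient(tt),
    stringsAsFactors = FALSE
  )
}

# One HT summary row in the layout of the per-homing results table.
.ht_summary_row <- function(frog_id, ht, window) {
  dur <- active_duration(ht, window)
  data.frame(
    frog_id = frog_id,
    tracked_distance_m = path_length(ht),
    straight_line_m = sum(.seg_lengths(ht$waypoints)),
    duration_h = dur,
    overnight = as.integer(as.Date(ht$fixes$t[nrow(ht$fixes)], tz = "UTC") >
                             as.Date(ht$fixes$t[1], tz = "UTC")),
    avg_speed_mh = mean_speed(ht, window),
    sc = straightness_coefficient(ht),
    complete = ht$complete,
    stringsAsFactors = FALSE
  )
}

#' Run the full trajectory analysis pipeline
#'
#' For every frog: derive the territory centre from territorial captures,
#' detect pool visits and infer depositions, split the track into
#' tadpole-transport (TT) and homing (HT) phases, and compute the
#' distance/duration/speed accounting and the three goal-directed precision
#' statistics. Phase-level Rayleigh tests pool the goal-relative deviation
#' angles across trajectories. Optionally fits the speed-versus-tadpole
#' mixed-model contrast (gamma family, log link, frog as random intercept)
#' and compares it against its null by AICc.
#'
#' Inputs may be file paths (the package CSV dialects) or data frames.
#'
#' @param fixes fixes table or path ([read_fixes()] dialect).
#' @param pools pool table or path ([read_pools()] dialect).
#' @param captures capture table or path ([read_captures()] dialect).
#' @param r_visit pool-visit radius (m). The default (2.5 m) is five times
#'   the nominal fix noise of the tracking protocol, so a dwelling frog is
#'   essentially never missed while pools 20 m apart stay unambiguous.
#' @param r_home returned-home radius (m) around the territory centre.
#' @param min_locations minimum fixes for the directionality analysis.
#' @param merge_gap_min visit gap-merging threshold (minutes).
#' @param window a [daylight_window()].
#' @param models fit the speed-versus-tadpole-presence model comparison.
#' @param out_dir if non-`NULL`, write `transport_summary.csv`,
#'   `homing_summary.csv`, `precision.csv`, `visits.csv` and `run_log.txt`
#'   there.
#' @return a `frog_analysis` list: `transport_summary`, `homing_summary`,
#'   `precision`, `visits`, `trajectories` (per frog TT/HT), `rayleigh`
#'   (per phase, pooled), `speed_model` (fit, null, comparison) and the
#'   threshold settings used.
#' @export
run_analyze <- function(fixes, pools, captures, r_visit = 2.5, r_home = 7,
                        min_locations = 4, merge_gap_min = 30,
                        window = daylight_window(), models = TRUE,
                        out_dir = NULL) {
  if (is.character(fixes)) fixes <- read_fixes(fixes)
  if (is.character(pools)) pools <- read_pools(pools)
  if (is.character(captures)) captures <- read_captures(captures)
  settings <- list(r_visit = r_visit, r_home = r_home,
                   min_locations = min_locations,
                   merge_gap_min = merge_gap_min,
                   day_start = sprintf("%02d:%02d", window$start_min %/% 60,
                                       window$start_min %% 60),
                   day_end = sprintf("%02d:%02d", window$end_min %/% 60,
                                     window$end_min %% 60))

  frog_ids <- unique(fixes$frog_id)
  tt_rows <- list(); ht_rows <- list(); prec_rows <- list()
  visit_rows <- list(); trajectories <- list()
  ang_pool <- list(TT = numeric(0), HT = numeric(0))
  for (id in frog_ids) {
    f <- fixes[fixes$frog_id == id, , drop = FALSE]
    cap <- captures[captures$frog_id == id, , drop = FALSE]
    if (nrow(cap) == 0 || !any(cap$territorial)) {
      warning("no territorial captures for frog ", id, "; skipped")
      next
    }
    terr <- territory_center(cap, frog_id = id)
    res <- .analyze_frog(f, pools, terr, r_visit, r_home, merge_gap_min,
                         window, min_locations)
    if (is.null(res)) {
      message("frog ", id, ": no deposition recorded; skipped")
      next
    }
    visit_rows[[id]] <- res$visits
    trajectories[[id]] <- res$seg
    if (!is.null(res$seg$TT)) {
      tt <- res$seg$TT
      tt_rows[[id]] <- .tt_summary_row(id, tt, res$tt_visits, window)
      pr <- precision_summary(tt, min_locations)
      prec_rows[[paste0(id, "-TT")]] <- pr
      if (pr$included) {
        ang_pool$TT <- c(ang_pool$TT, deviation_angles(tt))
      }
    }
    if (!is.null(res$seg$HT)) {
      ht <- res$seg$HT
      ht_rows[[id]] <- .ht_summary_row(id, ht, window)
      pr <- precision_summary(ht, min_locations)
      prec_rows[[paste0(id, "-HT")]] <- pr
      if (pr$included) {
        ang_pool$HT <- c(ang_pool$HT, deviation_angles(ht))
      }
    }
  }
  unrow <- function(df) { if (!is.null(df)) rownames(df) <- NULL; df }
  transport_summary <- unrow(do.call(rbind, tt_rows))
  homing_summary <- unrow(do.call(rbind, ht_rows))
  precision <- unrow(do.call(rbind, prec_rows))
  visits <- unrow(do.call(rbind, visit_rows))
  rayleigh <- lapply(ang_pool, function(a) {
    if (length(a) >= 4) rayleigh_test(a) else NULL
  })

  speed_model <- NULL
  if (models && !is.null(transport_summary) && !is.null(homing_summary)) {
    sp <- rbind(
      data.frame(frog_id = transport_summary$frog_id, tadpoles_present = 1,
                 speed = transport_summary$avg_speed_mh),
      data.frame(frog_id = homing_summary$frog_id, tadpoles_present = 0,
                 speed = homing_summary$avg_speed_mh)
    )
    if (length(unique(sp$frog_id)) >= 2 && nrow(sp) >= 6) {
      full <- fit_mixed_model("speed", "tadpoles_present", sp,
                              family = "gamma")
      null <- fit_mixed_model("speed", character(0), sp, family = "gamma")
      speed_model <- list(full = full, null = null,
                          comparison = compare_to_null(full, null),
                          data = sp)
    }
  }

  out <- structure(
    list(transport_summary = transport_summary,
         homing_summary = homing_summary, precision = precision,
         visits = visits, trajectories = trajectories, rayleigh = rayleigh,
         speed_model = speed_model, settings = settings),
    class = "frog_analysis"
  )
  if (!is.null(out_dir)) .write_analysis(out, out_dir)
  out
}

.write_analysis <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      df2 <- df
      for (cn in names(df2)) {
        if (inherits(df2[[cn]], "POSIXct")) df2[[cn]] <- .format_time(df2[[cn]])
      }
      write.table(df2, file.path(out_dir, name), sep = ",",
                  row.names = FALSE, quote = FALSE)
    }
  }
  wr(out$transport_summary, "transport_summary.csv")
  wr(out$homing_summary, "homing_summary.csv")
  wr(out$precision, "precision.csv")
  wr(out$visits, "visits.csv")
  log_lines <- c(
    sprintf("frogtraj %s", as.character(utils::packageVersion("frogtraj"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    vapply(names(out$settings), function(k)
      sprintf("%s = %s", k, out$settings[[k]]), character(1)),
    sprintf("frogs_analyzed = %d", length(out$trajectories))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.frog_analysis <- function(x, ...) {
  cat(sprintf("<frog_analysis> %d TT, %d HT trajectories, %d visits\n",
              if (is.null(x$transport_summary)) 0 else nrow(x$transport_summary),
              if (is.null(x$homing_summary)) 0 else nrow(x$homing_summary),
              if (is.null(x$visits)) 0 else nrow(x$visits)))
  invisible(x)
}
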