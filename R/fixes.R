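# Reading, validating and writing telemetry fixes.

.behavior_levels <- c("territorial", "transport", "other", "unknown")

.default_fix_map <- c(frog_id = "frog_id", timestamp = "timestamp",
                      x = "x_m", y = "y_m",
                      tadpoles = "tadpoles", behavior = "behavior")

#' Read telemetry fixes from a delimited text file
#'
#' A fix is one timestamped planar position of one frog, optionally annotated
#' with the number of tadpoles carried and a behavioural category. Coordinates
#' must be projected planar metres; longitude/latitude-looking input is
#' rejected. Fixes are grouped by frog and must be strictly increasing in time
#' within a frog.
#'
#' @param path path to a delimited text file with a header row.
#' @param col_map named character vector mapping the internal names
#'   `frog_id`, `timestamp`, `x`, `y` (required) and `tadpoles`, `behavior`
#'   (optional) to the column names in the file. Defaults to the package's
#'   own dialect (`frog_id`, `timestamp`, `x_m`, `y_m`, `tadpoles`,
#'   `behavior`).
#' @param delim field delimiter, default comma.
#' @return a `frog_fixes` data frame with columns `frog_id`, `t` (POSIXct,
#'   local clock time), `x`, `y` (metres), `tadpoles` (integer, `NA` =
#'   unknown) and `behavior` (one of territorial, transport, other, unknown),
#'   sorted by frog then time.
#' @export
read_fixes <- function(path, col_map = NULL, delim = ",") {
  map <- .default_fix_map
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (need in c("frog_id", "timestamp", "x", "y")) {
    if (!map[[need]] %in% names(raw)) {
      stop(sprintf("missing required column '%s' (mapped to '%s')",
                   map[[need]], need), call. = FALSE)
    }
  }
  fixes <- data.frame(
    frog_id = as.character(raw[[map[["frog_id"]]]]),
    t = .parse_time(raw[[map[["timestamp"]]]]),
    x = as.numeric(raw[[map[["x"]]]]),
    y = as.numeric(raw[[map[["y"]]]]),
    stringsAsFactors = FALSE
  )
  fixes$tadpoles <- if (map[["tadpoles"]] %in% names(raw)) {
    suppressWarnings(as.integer(raw[[map[["tadpoles"]]]]))
  } else NA_integer_
  fixes$behavior <- if (map[["behavior"]] %in% names(raw)) {
    b <- as.character(raw[[map[["behavior"]]]])
    b[is.na(b) | b == ""] <- "unknown"
    if (!all(b %in% .behavior_levels)) {
      stop("behavior values must be one of: ",
           paste(.behavior_levels, collapse = ", "), call. = FALSE)
    }
    b
  } else "unknown"
  validate_fixes(fixes)
}

#' Validate a fixes table
#'
#' Checks coordinate finiteness, rejects coordinates that look like
#' unprojected longitude/latitude, warns on tadpole loads outside the
#' plausible range, and enforces strictly increasing timestamps per frog.
#' Returns the table sorted by frog and time.
#'
#' @param fixes a data frame with columns `frog_id`, `t`, `x`, `y` and
#'   optionally `tadpoles`, `behavior`.
#' @return the validated, sorted `frog_fixes` data frame.
#' @export
validate_fixes <- function(fixes) {
  stopifnot(all(c("frog_id", "t", "x", "y") %in% names(fixes)))
  if (is.null(fixes$tadpoles)) fixes$tadpoles <- NA_integer_
  if (is.null(fixes$behavior)) fixes$behavior <- "unknown"
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y))) {
    stop("non-finite coordinates in fixes", call. = FALSE)
  }
  if (nrow(fixes) > 0 &&
      all(abs(fixes$x) <= 180) && all(abs(fixes$y) <= 90)) {
    stop("coordinates look like longitude/latitude; ",
         "project to planar metres (e.g. UTM) before reading", call. = FALSE)
  }
  known <- !is.na(fixes$tadpoles)
  if (any(fixes$tadpoles[known] < 0)) {
    stop("negative tadpole counts", call. = FALSE)
  }
  if (any(fixes$tadpoles[known] > 25)) {
    warning("tadpole counts above 25 exceed the plausible load range")
  }
  # order check runs on the rows as supplied, so shuffled input is an error
  # rather than being silently repaired
  bad <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$frog_id), function(i) {
    if (length(i) < 2) return(integer(0))
    i[-1][diff(as.numeric(fixes$t[i])) <= 0]
  }))
  if (length(bad)) {
    stop("timestamps not strictly increasing within frog at row(s): ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  fixes <- fixes[order(fixes$frog_id, fixes$t), , drop = FALSE]
  rownames(fixes) <- NULL
  class(fixes) <- c("frog_fixes", "data.frame")
  fixes
}

#' Write fixes back to the package's CSV dialect
#'
#' @param fixes a fixes data frame as returned by [read_fixes()].
#' @param path output file path.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path, delim = ",") {
  out <- data.frame(frog_id = fixes$frog_id,
                    timestamp = .format_time(fixes$t),
                    x_m = fixes$x, y_m = fixes$y,
                    tadpoles = fixes$tadpoles, behavior = fixes$behavior)
  write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
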