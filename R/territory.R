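# Territory centres from capture data.

#' Read territory capture records
#'
#' Capture table dialect: `frog_id`, `timestamp`, `x_m`, `y_m`,
#' `territorial` (0/1 flag marking captures at which the male displayed
#' territorial behaviour: calling, courtship, aggression).
#'
#' @param path path to the capture CSV.
#' @param delim field delimiter, default comma.
#' @return a data frame with columns `frog_id`, `t`, `x`, `y`, `territorial`
#'   (logical).
#' @export
read_captures <- function(path, delim = ",") {
  raw <- read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (need in c("frog_id", "x_m", "y_m", "territorial")) {
    if (!need %in% names(raw)) {
      stop(sprintf("missing required column '%s' in capture table", need),
           call. = FALSE)
    }
  }
  data.frame(
    frog_id = as.character(raw$frog_id),
    t = if ("timestamp" %in% names(raw)) .parse_time(raw$timestamp) else
      as.POSIXct(NA),
    x = as.numeric(raw$x_m), y = as.numeric(raw$y_m),
    territorial = as.logical(as.integer(raw$territorial)),
    stringsAsFactors = FALSE
  )
}

#' Compute a territory centre from capture points
#'
#' The territory centre is the unweighted arithmetic centroid of the capture
#' points at which the male displayed territorial behaviour; captures without
#' territorial behaviour are ignored.
#'
#' @param captures either a numeric matrix/data frame of capture coordinates
#'   (columns x, y) or a capture data frame as returned by [read_captures()].
#' @param territorial logical vector flagging territorial-behaviour captures;
#'   taken from `captures$territorial` when present and otherwise assumed all
#'   `TRUE`.
#' @param frog_id identifier attached to the result.
#' @return a `frog_territory` object: list with `frog_id`, `center`
#'   (named numeric `c(x, y)`) and `n_captures` (points used).
#' @examples
#' territory_center(rbind(c(0, 0), c(2, 0), c(1, 3)))
#' @export
territory_center <- function(captures, territorial = NULL, frog_id = NA_character_) {
  if (is.data.frame(captures) && all(c("x", "y") %in% names(captures))) {
    if (is.null(territorial) && !is.null(captures$territorial)) {
      territorial <- captures$territorial
    }
    xy <- cbind(captures$x, captures$y)
  } else {
    xy <- as.matrix(captures)
  }
  if (is.null(territorial)) territorial <- rep(TRUE, nrow(xy))
  stopifnot(length(territorial) == nrow(xy))
  xy <- xy[territorial & !is.na(territorial), , drop = FALSE]
  if (nrow(xy) == 0) stop("no territorial captures", call. = FALSE)
  structure(
    list(frog_id = frog_id,
         center = c(x = mean(xy[, 1]), y = mean(xy[, 2])),
         n_captures = nrow(xy)),
    class = "frog_territory"
  )
}

#' @export
print.frog_territory <- function(x, ...) {
  cat(sprintf("Territory of %s: centre (%.2f, %.2f) m from %d captures\n",
              x$frog_id, x$center[1], x$center[2], x$n_captures))
  invisible(x)
}
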