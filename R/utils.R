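# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between two points given as length-2 vectors.
.dist2 <- function(a, b) sqrt(sum((a - b)^2))

# Segment lengths of an n x 2 coordinate matrix.
.seg_lengths <- function(xy) {
  if (nrow(xy) < 2) return(numeric(0))
  sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
}

# Distance from point p to the segment a-b, either to the infinite line
# through a and b or clamped to the segment ends.
.point_line_dist <- function(p, a, b, clamp = FALSE) {
  v <- b - a
  len2 <- sum(v^2)
  if (len2 == 0) stop("degenerate chord: identical waypoints", call. = FALSE)
  if (clamp) {
    t <- max(0, min(1, sum((p - a) * v) / len2))
    .dist2(p, a + t * v)
  } else {
    abs(v[1] * (p[2] - a[2]) - v[2] * (p[1] - a[1])) / sqrt(len2)
  }
}

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Every stochastic operation in the simulator draws from its own named
#' sub-stream so that adding new operations never perturbs existing fixtures.
#' The label is hashed onto the 32-bit integer range and folded into the
#' master seed.
#'
#' @param seed master integer seed.
#' @param name character label of the sub-stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

# Evaluate expr under a named RNG sub-stream, restoring the RNG state after.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(substream_seed(seed, name))
  expr
}

# Strict ISO-8601-ish timestamp parser (local clock time, no timezone
# semantics; stored as UTC so arithmetic is plain clock arithmetic).
.parse_time <- function(x) {
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  out
}

.format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
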