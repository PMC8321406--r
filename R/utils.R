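#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across
#' @importFrom stats rnorm runif rpois median mad quantile sd wilcox.test
#'   approx setNames
#' @importFrom utils head tail
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap an angle (deg) into (-180, 180]
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

## wrap into [0, 360)
wrap360 <- function(a) a %% 360

## fold an orientation difference (deg) into [0, 90]
fold90 <- function(a) {
  a <- abs(a) %% 180
  pmin(a, 180 - a)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## circular gaps between k ray directions (deg); sums to 360 by construction
circular_gaps <- function(dirs) {
  d <- sort(wrap360(dirs))
  k <- length(d)
  gaps <- c(diff(d), 360 - d[k] + d[1])
  gaps
}

## sorted angle triplet from three ray directions
sorted_triplet <- function(dirs) sort(circular_gaps(dirs))

## Deterministic substream seed derived from a master seed and a stream name.
## Keeps derived seeds in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% (2^31 - 2) + 1)
}

## run expr with a local RNG state seeded by `seed` (restores caller RNG)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## polyline arclength (matrix with columns x, y)
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

## cumulative arclength along a polyline
polyline_cumlen <- function(p) {
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)))
}

## moving-average smoother that shrinks the window near the ends
smooth_ma <- function(x, k) {
  if (k <= 1 || length(x) < 3) return(x)
  n <- length(x)
  half <- floor(k / 2)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}
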