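#' Sample a seed landing patch
#'
#' The landing distance follows a negative exponential density (mean
#' \code{lambdaSeed}, truncated at \code{seedRadius}), the direction is
#' uniform, and the destination is the patch containing the displaced
#' point. Destinations outside the grid are lost (absorbing boundary) and
#' returned as NA.
#'
#' @param origin integer(2), 0-based patch coordinates of the mother
#' @param config a [SimConfig-class]
#' @param gridDim integer(2) grid width and height
#' @return integer(2) destination patch, or NULL when the seed leaves the
#'   grid
#' @export
sampleSeedDestination <- function(origin, config = simConfig(),
                                  gridDim = c(100L, 100L)) {
  p <- config@params
  d <- rexp(1L, rate = 1 / p$lambdaSeed)
  tries <- 0L
  while (d > p$seedRadius && tries < 100L) {
    d <- rexp(1L, rate = 1 / p$lambdaSeed)
    tries <- tries + 1L
  }
  a <- runif(1L, 0, 2 * pi)
  x <- as.integer(round(origin[1] + d * cos(a)))
  y <- as.integer(round(origin[2] + d * sin(a)))
  if (x < 0L || y < 0L || x >= gridDim[1] || y >= gridDim[2]) return(NULL)
  c(x, y)
}

#' Settle competing seeds onto free patches
#'
#' All seeds of a cycle are settled simultaneously: seeds landing on an
#' occupied patch or a patch unsuitable for their cytotype are discarded;
#' among seeds contending for one free suitable patch the one with the
#' highest prospective fitness E establishes (ties broken uniformly at
#' random). This is the pure-R reference used by the unit tests; the engine
#' applies the identical rule.
#'
#' @param destinations integer matrix n x 2 of 0-based landing patches
#' @param prospectiveE numeric(n) fitness of each seed on its landing patch
#' @param free logical width x height matrix: patch currently unoccupied
#' @param suitable logical n: landing patch suitable for the seed
#' @return integer vector of winning seed indices
#' @export
settleSeeds <- function(destinations, prospectiveE, free, suitable) {
  n <- nrow(destinations)
  ok <- which(suitable &
              free[cbind(destinations[, 1] + 1L, destinations[, 2] + 1L)])
  if (!length(ok)) return(integer())
  key <- destinations[ok, 1] * nrow(free) * 4L + destinations[ok, 2]
  winners <- integer()
  for (k in unique(key)) {
    contenders <- ok[key == k]
    e <- prospectiveE[contenders]
    best <- contenders[e == max(e)]
    winners <- c(winners,
                 if (length(best) == 1L) best
                 else best[sample.int(length(best), 1L)])
  }
  winners
}
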