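#' Deterministic diploid/tetraploid gametic recursion
#'
#' Random union of gametes in an infinite hermaphroditic population with
#' inviable triploids: diploids contribute reduced (x) gametes with
#' frequency 1 - p and unreduced (2x) with frequency p; tetraploids
#' contribute reduced (2x) gametes, weighted by their relative fertility.
#' Offspring from x + x are diploid, from 2x + 2x tetraploid (weighted by
#' relative viability), and x + 2x triploids are discarded. Iterating this
#' map from a diploid population either reaches a mixed equilibrium or
#' excludes the diploid, depending on p.
#'
#' @param p unreduced gamete frequency in diploids
#' @param fertility4x,viability4x fertility and viability of the tetraploid
#'   relative to the diploid
#' @param init initial cytotype frequencies c(d = , t = )
#' @param generations iterations of the map
#' @return matrix with columns \code{d} (2x) and \code{t} (4x), one row per
#'   generation including the initial state
#' @export
iterateRecursion <- function(p, fertility4x = 1, viability4x = 1,
                             init = c(d = 1, t = 0), generations = 100L) {
  stopifnot(p >= 0, p <= 1, abs(sum(init) - 1) < 1e-12)
  out <- matrix(NA_real_, generations + 1L, 2,
                dimnames = list(NULL, c("d", "t")))
  d <- init[["d"]]; t4 <- init[["t"]]
  out[1L, ] <- c(d, t4)
  for (g in seq_len(generations)) {
    w <- d + t4 * fertility4x
    gx <- d * (1 - p) / w
    g2 <- (d * p + t4 * fertility4x) / w
    o2 <- gx^2
    o4 <- viability4x * g2^2
    tot <- o2 + o4
    if (tot == 0) { out[g + 1L, ] <- c(d, t4); next }
    d <- o2 / tot; t4 <- o4 / tot
    out[g + 1L, ] <- c(d, t4)
  }
  out
}

.recursionExcludes <- function(p, fertility4x, viability4x,
                               generations = 200000L, eps = 1e-6) {
  d <- 1; t4 <- 0
  for (g in seq_len(generations)) {
    w <- d + t4 * fertility4x
    gx <- d * (1 - p) / w
    g2 <- (d * p + t4 * fertility4x) / w
    o2 <- gx^2
    o4 <- viability4x * g2^2
    dn <- o2 / (o2 + o4)
    if (abs(dn - d) < 1e-14 && g > 100L) { d <- dn; break }
    d <- dn; t4 <- 1 - dn
  }
  d < eps
}

#' Critical unreduced-gamete rate for diploid exclusion
#'
#' For the deterministic recursion, locates by bisection the smallest p at
#' which iteration of the gametic map drives the diploid frequency to zero
#' (above the threshold the tetraploid excludes the diploid; below it a
#' mixed population persists). For the agent-based variant, runs the
#' simulator under the classical-comparison preset ([felberConfig()]) over
#' a grid of p values and reports the smallest p at which diploids go
#' extinct in a majority of replicates.
#'
#' @param variant "deterministic" or "abm"
#' @param fertility4x,viability4x relative tetraploid fertility/viability
#'   (deterministic variant)
#' @param scan numeric(2) search interval for p (both variants)
#' @param tol bisection tolerance on p (deterministic variant)
#' @param step scan step (abm variant)
#' @param nrep replicates per scanned p (abm variant)
#' @param grid environment for the abm variant; the default is a uniform
#'   32 x 32 workspace whose carrying capacity (~1000 plants) matches the
#'   census scale of the classical comparison
#' @param config base configuration for the abm variant; defaults to
#'   [felberConfig()]
#' @param seed root seed (abm variant)
#' @return the critical p (proportion); for the abm variant, NA when no
#'   scanned rate excluded diploids in a majority of replicates, with the
#'   per-rate exclusion fractions in attribute \code{"scan"}
#' @export
findExclusionThreshold <- function(variant = c("deterministic", "abm"),
                                   fertility4x = 1, viability4x = 1,
                                   scan = c(0.05, 0.30), tol = 2e-4,
                                   step = 0.005, nrep = 5L,
                                   grid = NULL, config = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "deterministic") {
    lo <- scan[1]; hi <- scan[2]
    if (.recursionExcludes(lo, fertility4x, viability4x))
      stop("scan lower bound already excludes diploids; widen the scan")
    if (!.recursionExcludes(hi, fertility4x, viability4x))
      stop("scan upper bound does not exclude diploids; widen the scan")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.recursionExcludes(mid, fertility4x, viability4x)) hi <- mid
      else lo <- mid
    }
    return((lo + hi) / 2)
  }
  if (is.null(grid))
    grid <- generateSyntheticEnvironment(
      syntheticEnvSpec(width = 32L, height = 32L, amplitudes = rep(0, 5),
                       trends = rep(0, 5)),
      seed = 1L)
  if (is.null(config)) config <- felberConfig()
  ps <- seq(scan[1], scan[2], by = step)
  excl <- numeric(length(ps))
  for (i in seq_along(ps)) {
    cfgI <- updateConfig(config, unreducedRate2x = ps[i])
    hits <- 0L
    for (r in seq_len(nrep)) {
      rep <- runReplicate(grid, cfgI,
                          seed = .replicateSeed(seed, "felber", i, r))
      s <- replicateSummary(rep)
      # diploid exclusion: no diploids left standing at stop
      if (s$stop_reason == "fixation" ||
          (s$final_census > 0 && s$final_4x_proportion == 1) ||
          s$stop_reason == "extinct") hits <- hits + 1L
    }
    excl[i] <- hits / nrep
  }
  crit <- ps[which(excl > 0.5)]
  out <- if (length(crit)) min(crit) else NA_real_
  attr(out, "scan") <- data.frame(p = ps, exclusion_fraction = excl)
  out
}
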