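#' Gamete class distribution of a cytotype
#'
#' Diploids produce reduced (x) gametes, and unreduced (2x) gametes at the
#' configured rate once unreduced production has switched on; triploids
#' produce a mix of reduced x, reduced 2x, unreduced 3x and aneuploid
#' gametes; tetraploids produce reduced 2x gametes and (optionally)
#' unreduced 4x gametes. Female and male gametes follow the same
#' distribution.
#'
#' @param ploidy 2, 3 or 4
#' @param config a [SimConfig-class]
#' @param generation current generation; before \code{onsetGeneration} the
#'   diploid unreduced rate is forced to 0. Default is past onset.
#' @return data.frame with columns \code{dosage} (multiples of x; NA for
#'   aneuploid), \code{klass} (reduced/unreduced/aneuploid) and \code{prob}.
#' @export
gameteClassDistribution <- function(ploidy, config = simConfig(),
                                    generation = Inf) {
  p <- config@params
  switch(as.character(ploidy),
    "2" = {
      r <- if (generation < p$onsetGeneration) 0 else p$unreducedRate2x
      data.frame(dosage = c(1, 2),
                 klass = c("reduced", "unreduced"),
                 prob = c(1 - r, r))
    },
    "3" = data.frame(dosage = c(1, 2, 3, NA),
                     klass = c("reduced", "reduced", "unreduced", "aneuploid"),
                     prob = as.numeric(p$triploidGameteMix)),
    "4" = data.frame(dosage = c(2, 4),
                     klass = c("reduced", "unreduced"),
                     prob = c(1 - p$unreducedRate4x, p$unreducedRate4x)),
    stop("ploidy must be 2, 3 or 4")
  )
}

#' Sample gametes from a cytotype's distribution
#'
#' @inheritParams gameteClassDistribution
#' @param n number of gametes
#' @return data.frame with columns \code{dosage} and \code{klass}
#' @export
sampleGametes <- function(n, ploidy, config = simConfig(),
                          generation = Inf) {
  d <- gameteClassDistribution(ploidy, config, generation)
  i <- sample.int(nrow(d), n, replace = TRUE, prob = d$prob)
  data.frame(dosage = d$dosage[i], klass = d$klass[i])
}

#' Choose the reproductive pathway of one or more ovules
#'
#' Independent categorical draws: selfing with the bearer cytotype's
#' selfing rate, apomixis with its apomixis rate, otherwise outcrossing.
#'
#' @param n number of ovules
#' @param ploidy bearer cytotype (2, 3 or 4)
#' @param config a [SimConfig-class]
#' @return character vector in \code{c("outcross","self","apomixis")}
#' @export
choosePathway <- function(n, ploidy, config = simConfig()) {
  p <- config@params
  key <- paste0(ploidy, "x")
  s <- p$selfingRates[[key]]; a <- p$apomixisRates[[key]]
  u <- runif(n)
  ifelse(u < s, "self", ifelse(u < s + a, "apomixis", "outcross"))
}

#' Select a pollen donor for an outcrossing ovule
#'
#' Among living plants other than the mother within the pollen neighborhood
#' radius, one donor is drawn with probability proportional to
#' \code{exp(-d / lambdaPollen)} where d is the Euclidean distance between
#' patch centres. Returns NA when no candidate exists (pollen limitation:
#' the ovule aborts).
#'
#' @param mother index of the mother in the coordinate vectors
#' @param x,y 0-based coordinates of all living plants
#' @param config a [SimConfig-class]
#' @return the donor's index, or NA
#' @export
selectPollenDonor <- function(mother, x, y, config = simConfig()) {
  p <- config@params
  d <- sqrt((x - x[mother])^2 + (y - y[mother])^2)
  cand <- which(d <= p$pollenRadius & seq_along(x) != mother)
  if (!length(cand)) return(NA_integer_)
  if (isTRUE(p$globalPollen)) {
    cand <- setdiff(seq_along(x), mother)
    return(cand[sample.int(length(cand), 1L)])
  }
  w <- exp(-d[cand] / p$lambdaPollen)
  cand[sample.int(length(cand), 1L, prob = w)]
}

#' Ploidy of a sexual seed from two gametes
#'
#' The seed's ploidy is the sum of the gamete dosages; any aneuploid gamete
#' or a sum above 4x gives an inviable seed (NA).
#'
#' @param female,male rows as returned by [sampleGametes()] (fields
#'   \code{dosage}, \code{klass})
#' @return integer ploidy in \code{2:4}, or NA for an inviable combination
#' @export
seedPloidy <- function(female, male) {
  if (identical(female$klass, "aneuploid") ||
      identical(male$klass, "aneuploid")) return(NA_integer_)
  s <- female$dosage + male$dosage
  if (is.na(s) || s < 2 || s > 4) return(NA_integer_) else as.integer(s)
}

#' Classify a polyploidization event by its gametes
#'
#' Bilateral events unite two unreduced gametes (2n + 2n); unilateral events
#' unite one unreduced with one reduced gamete (2n + n). Fusions of two
#' reduced gametes are not unreduced-gamete events ("none"), even when the
#' offspring is polyploid. Only seeds whose ploidy exceeds the parental
#' baseline (a 3x or 4x seed from parents that are not both tetraploid)
#' are logged as events by the engine.
#'
#' @inheritParams seedPloidy
#' @return "bilateral", "unilateral" or "none"
#' @export
classifyPolyploidization <- function(female, male) {
  nu <- sum(c(identical(female$klass, "unreduced"),
              identical(male$klass, "unreduced")))
  c("none", "unilateral", "bilateral")[nu + 1L]
}

#' Offspring adaptive optimum
#'
#' Sexual offspring take the mid-parent value of each trait component, plus
#' optional Gaussian segregation noise (sd 0 by default: pure blending
#' inheritance, which removes drift in the trait values). Apomictic
#' offspring are exact maternal copies.
#'
#' @param pathway "outcross", "self" or "apomixis"
#' @param motherIa numeric(5)
#' @param fatherIa numeric(5); required for sexual pathways
#' @param segregationSd Gaussian sd per component
#' @return numeric(5)
#' @export
inheritAdaptivity <- function(pathway, motherIa, fatherIa = NULL,
                              segregationSd = 0) {
  if (pathway == "apomixis") return(motherIa)
  if (is.null(fatherIa)) stop("sexual inheritance requires a father")
  mid <- (motherIa + fatherIa) / 2
  if (segregationSd > 0) mid <- mid + rnorm(length(mid), 0, segregationSd)
  mid
}

#' Pick the shifted-optimum patch set for tetraploids
#'
#' Selects \code{n} patches whose centroid lies at (approximately) the
#' requested Euclidean distance from the centroid of the founder area, by
#' sampling patches uniformly within a narrow annulus around that distance.
#' The returned matrix of layer values parameterises the shifted-optimum
#' experiments: each newly minted tetraploid lineage founder has its
#' adaptive optimum matched to one of these patches.
#'
#' @param grid an [EnvironmentGrid-class]
#' @param distance target shift in patches (0 reduces to the shared-optimum
#'   model: patches are drawn from the founder block itself)
#' @param n number of optimum patches (30)
#' @param halfWidth annulus half-width in patches
#' @return an n x 5 matrix of layer values, with the patch coordinates in
#'   attributes \code{x} and \code{y}
#' @export
chooseOptimumPatches <- function(grid, distance, n = 30L, halfWidth = 2) {
  nx <- gridWidth(grid); ny <- gridHeight(grid)
  cx <- nx %/% 2L; cy <- ny %/% 2L
  xs <- rep(0:(nx - 1L), times = ny)
  ys <- rep(0:(ny - 1L), each = nx)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  keep <- if (distance <= halfWidth) d <= max(distance + halfWidth, 3.2)
          else abs(d - distance) <= halfWidth
  idx <- which(keep)
  if (length(idx) < n)
    stop("annulus at distance ", distance, " holds fewer than ", n, " patches")
  pick <- idx[sample.int(length(idx), n)]
  out <- matrix(0, n, 5)
  for (k in seq_len(n))
    out[k, ] <- envLayers(grid)[xs[pick[k]] + 1L, ys[pick[k]] + 1L, ]
  attr(out, "x") <- xs[pick]; attr(out, "y") <- ys[pick]
  out
}
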