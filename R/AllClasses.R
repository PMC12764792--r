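#' EnvironmentGrid: the five-layer patch lattice
#'
#' A rectangular lattice of square habitat patches (default 100 x 100 patches
#' of 0.25 m^2). Each patch carries five scalar environmental variables:
#' three "bioclimatic" layers (V1-V3), which in real landscapes are nearly
#' uniform at this micro scale and are additionally perturbed each generation
#' by a global seasonal factor, and two "soil" layers (V4-V5) whose spatial
#' patchiness is what restricts the occupiable area.
#'
#' Layers are stored as a numeric array of dimension \code{c(width, height,
#' 5)}; patch coordinates are 0-based integers with the origin at the
#' lower-left corner, so layer value for patch (x, y) is
#' \code{envLayers(g)[x + 1, y + 1, i]}.
#'
#' @slot width,height integer patch counts.
#' @slot layers numeric array \code{c(width, height, 5)}; all values finite.
#' @slot patchArea patch area in m^2 (default 0.25).
#' @slot layerNames character(5), informative labels for V1-V5.
#'
#' @seealso [generateSyntheticEnvironment()], [loadCsvEnvironment()]
#' @export
setClass("EnvironmentGrid",
  representation(
    width = "integer",
    height = "integer",
    layers = "array",
    patchArea = "numeric",
    layerNames = "character"
  ),
  prototype(patchArea = 0.25)
)

setValidity("EnvironmentGrid", function(object) {
  msgs <- character()
  d <- dim(object@layers)
  if (length(d) != 3L || d[3] != 5L)
    msgs <- c(msgs, "layers must be a width x height x 5 array")
  else {
    if (d[1] != object@width || d[2] != object@height)
      msgs <- c(msgs, "layer dimensions do not match width/height")
    if (!all(is.finite(object@layers)))
      msgs <- c(msgs, "layer values must be finite")
  }
  if (object@width < 1L || object@height < 1L)
    msgs <- c(msgs, "grid must have positive dimensions")
  if (length(object@patchArea) != 1L || object@patchArea <= 0)
    msgs <- c(msgs, "patchArea must be a positive scalar")
  if (length(object@layerNames) != 5L)
    msgs <- c(msgs, "layerNames must have length 5")
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: one simulation run configuration
#'
#' All tunable parameters of a replicate. Constructed with [simConfig()],
#' which documents every field and its default; the class enforces the
#' probability and positivity constraints.
#'
#' @slot params named list of parameter values (see [simConfig()]).
#' @export
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msgs <- character()
  need <- c(
    "svSd", "limits", "limitMultiplier4x", "combineRule",
    "mortality", "fecundityCaps", "baseLifespan",
    "nFounders", "founderBlock",
    "unreducedRate2x", "unreducedRate4x", "triploidGameteMix",
    "triploidSeedViability", "onsetGeneration",
    "selfingRates", "apomixisRates",
    "lambdaPollen", "pollenRadius", "lambdaSeed", "seedRadius",
    "establishmentThreshold", "horizonGenerations",
    "segregationSd", "uniformE", "globalPollen", "optimumPatches"
  )
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(paste("missing config fields:", paste(miss, collapse = ", ")))
  chkProb <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      msgs <<- c(msgs, paste(nm, "must lie in [0,1]"))
  }
  chkProb(p$unreducedRate2x, "unreducedRate2x")
  chkProb(p$unreducedRate4x, "unreducedRate4x")
  chkProb(p$mortality, "mortality")
  chkProb(p$triploidSeedViability, "triploidSeedViability")
  chkProb(p$selfingRates, "selfingRates")
  chkProb(p$apomixisRates, "apomixisRates")
  if (any(p$selfingRates + p$apomixisRates > 1 + 1e-12))
    msgs <- c(msgs, "selfingRates + apomixisRates must be <= 1 per cytotype")
  if (length(p$triploidGameteMix) != 4L ||
      abs(sum(p$triploidGameteMix) - 1) > 1e-9 ||
      any(p$triploidGameteMix < 0))
    msgs <- c(msgs, "triploidGameteMix must be 4 non-negative probabilities summing to 1")
  if (length(p$limits) != 5L || any(p$limits <= 0))
    msgs <- c(msgs, "limits must be 5 positive tolerance half-widths")
  if (p$limitMultiplier4x <= 0)
    msgs <- c(msgs, "limitMultiplier4x must be positive")
  if (p$lambdaPollen <= 0 || p$lambdaSeed <= 0)
    msgs <- c(msgs, "dispersal kernel means must be positive")
  if (p$pollenRadius < 1 || p$seedRadius < 1)
    msgs <- c(msgs, "kernel truncation radii must be >= 1")
  if (!identical(sort(names(p$selfingRates)), sort(c("2x", "3x", "4x"))))
    msgs <- c(msgs, "selfingRates must be named '2x','3x','4x'")
  if (!p$combineRule %in% c("geometric", "product", "min"))
    msgs <- c(msgs, "combineRule must be one of geometric/product/min")
  if (!is.na(p$uniformE)) chkProb(p$uniformE, "uniformE")
  if (length(msgs)) msgs else TRUE
})

#' ReplicateResult: output of one simulated replicate
#'
#' @slot summary one-row data.frame of run statistics: counts of successful
#'   (SPE) and unsuccessful (UPE) polyploidization events, bilateral and
#'   unilateral event counts, generations from the first successful event's
#'   formation to its establishment (GPIP), generations from onset of
#'   unreduced gamete production to tetraploid fixation (GuF, NA when
#'   fixation was not reached), the final tetraploid proportion, stop reason
#'   and seed.
#' @slot events data.frame, one row per polyploidization event (type,
#'   formation generation, location, founder fitness, outcome).
#' @slot census data.frame of per-generation cytotype counts and the
#'   seasonal factor drawn that generation (empty unless requested).
#' @slot config the [SimConfig-class] used.
#' @slot seed integer root seed of the replicate.
#' @export
setClass("ReplicateResult",
  representation(
    summary = "data.frame",
    events = "data.frame",
    census = "data.frame",
    config = "SimConfig",
    seed = "integer"
  )
)

setMethod("show", "EnvironmentGrid", function(object) {
  cat("EnvironmentGrid:", object@width, "x", object@height,
      "patches of", object@patchArea, "m^2\n")
  rng <- apply(object@layers, 3, range)
  for (i in 1:5)
    cat(sprintf("  V%d (%s): %.4g .. %.4g\n", i, object@layerNames[i],
                rng[1, i], rng[2, i]))
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig\n")
  cat(sprintf("  unreduced 2n rate (2x): %.4g  onset generation: %d\n",
              p$unreducedRate2x, p$onsetGeneration))
  cat(sprintf("  selfing (2x/3x/4x): %s   apomixis: %s\n",
              paste(p$selfingRates, collapse = "/"),
              paste(p$apomixisRates, collapse = "/")))
  cat(sprintf("  tolerance limits: %s  x%.2f for 4x\n",
              paste(signif(p$limits, 3), collapse = ", "),
              p$limitMultiplier4x))
  cat(sprintf("  kernels: pollen exp(-d/%.2f) <= %d, seed Exp(%.2f) <= %d\n",
              p$lambdaPollen, p$pollenRadius, p$lambdaSeed, p$seedRadius))
  cat(sprintf("  establishment threshold: %d   horizon: %d generations\n",
              p$establishmentThreshold, p$horizonGenerations))
})

setMethod("show", "ReplicateResult", function(object) {
  s <- object@summary
  cat("ReplicateResult (seed", object@seed, ")\n")
  cat(sprintf("  stop: %s at generation %d; final 4x proportion %.3f\n",
              s$stop_reason, s$final_generation, s$final_4x_proportion))
  cat(sprintf("  events: %d bilateral + %d unilateral = %d SPE + %d UPE\n",
              s$bilateral_count, s$unilateral_count, s$spe_count, s$upe_count))
  if (!is.na(s$gpip)) cat(sprintf("  GPIP %d", s$gpip))
  if (!is.na(s$guf)) cat(sprintf("  GuF %d", s$guf))
  if (!is.na(s$gpip) || !is.na(s$guf)) cat("\n")
})

#' @describeIn EnvironmentGrid-class grid width in patches
#' @param x an \code{EnvironmentGrid}
#' @export
gridWidth <- function(x) x@width

#' @describeIn EnvironmentGrid-class grid height in patches
#' @export
gridHeight <- function(x) x@height

#' @describeIn EnvironmentGrid-class the width x height x 5 layer array
#' @export
envLayers <- function(x) x@layers

#' @describeIn EnvironmentGrid-class patch area in m^2
#' @export
patchArea <- function(x) x@patchArea

#' Accessors for replicate results
#'
#' @param x a [ReplicateResult-class]
#' @return `replicateSummary()` the one-row summary data.frame;
#'   `eventRecords()` the event table; `censusRecords()` the per-generation
#'   census (empty unless recording was requested).
#' @export
replicateSummary <- function(x) x@summary

#' @rdname replicateSummary
#' @export
eventRecords <- function(x) x@events

#' @rdname replicateSummary
#' @export
censusRecords <- function(x) x@census

#' @rdname replicateSummary
#' @export
simConfigOf <- function(x) x@config
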