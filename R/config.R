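#' Build a simulation configuration
#'
#' Collects every tunable parameter of a replicate into a validated
#' [SimConfig-class]. Defaults encode the baseline study conditions: a
#' perennial, self-sterile outcrossing diploid population with a natural
#' unreduced-gamete rate of 0.6\% switching on at generation 200, partially
#' viable and fertile triploids, equal diploid/tetraploid tolerance, and
#' short-range pollen and seed movement.
#'
#' @param svSd standard deviation of the global seasonal factor multiplying
#'   V1-V3 each generation (Gaussian, mean 1).
#' @param limits numeric(5), ecological tolerance half-widths LimitV1..LimitV5
#'   of diploids and triploids, in the units of the corresponding layer. A
#'   deviation equal to the limit halves that fitness component. Defaults are
#'   calibrated to the packaged synthetic environment (see
#'   [syntheticEnvSpec()]).
#' @param limitMultiplier4x scalar k: tetraploid tolerance is k x the
#'   diploid limits (the swept variable of the tolerance experiments).
#' @param combineRule how the five per-variable fitness components combine
#'   into E: "geometric" (default), "product", or "min".
#' @param mortality per-cycle background death probability (0.10).
#' @param fecundityCaps integer(3): maximum offspring at age 1, 2, and >= 3.
#' @param baseLifespan maximum lifespan in cycles at establishment fitness 1;
#'   an individual's cap is \code{ceiling(baseLifespan * E)} at establishment.
#' @param nFounders number of diploid founders (30).
#' @param founderBlock side, in patches, of the central square in which
#'   founders are placed (20).
#' @param unreducedRate2x probability that a diploid gamete is unreduced
#'   (2n = 2x), once past \code{onsetGeneration}.
#' @param unreducedRate4x probability that a tetraploid gamete is unreduced
#'   (2n = 4x); such gametes can only form inviable (> 4x) fusions.
#' @param triploidGameteMix probabilities over triploid gamete classes,
#'   named \code{c(x=, "2x"=, "3x"=, aneuploid=)}.
#' @param triploidSeedViability multiplicative viability of any seed that is
#'   triploid or has a triploid parent (the scalar triploid block).
#' @param onsetGeneration generation at which unreduced gamete production
#'   switches on (200); earlier generations are diploid burn-in.
#' @param selfingRates,apomixisRates named numeric(3) (\code{"2x","3x","4x"}):
#'   per-ovule probability of the selfing / apomictic pathway by bearer
#'   cytotype; the remainder outcrosses. Baseline is fully self-sterile.
#' @param lambdaPollen decay length (patches) of the exponential
#'   distance weight for pollen-donor choice; \code{pollenRadius} truncates
#'   the donor neighborhood.
#' @param pollenRadius hard pollen neighborhood radius in patches.
#' @param lambdaSeed mean of the negative exponential seed dispersal
#'   distance (patches); \code{seedRadius} truncates it.
#' @param seedRadius hard seed dispersal truncation in patches.
#' @param establishmentThreshold living tetraploids descended from one
#'   polyploidization event required to call the event successful (50).
#' @param horizonGenerations generations simulated past
#'   \code{onsetGeneration} before a run stops without fixation (1000).
#' @param segregationSd Gaussian sd added to each mid-parent trait component
#'   at sexual inheritance (0: pure blending, no segregation variance).
#' @param uniformE \code{NA} (default) for environment-driven fitness, or a
#'   value in (0,1] that overrides E everywhere (homogeneous-environment
#'   mode; every patch is then suitable).
#' @param globalPollen if TRUE the pollen donor is drawn uniformly from all
#'   living plants (panmixis) instead of the distance-weighted neighborhood.
#' @param optimumPatches NULL, or an n x 5 matrix of layer values; when set,
#'   every newly minted tetraploid lineage founder has its adaptive optimum
#'   replaced by one uniformly chosen row (the shifted-optimum experiments).
#' @param ... override any field by name.
#' @return a validated [SimConfig-class]
#' @export
simConfig <- function(svSd = 1e-3,
                      limits = c(4.5, 1.4, 28, 0.70, 0.45),
                      limitMultiplier4x = 1,
                      combineRule = "geometric",
                      mortality = 0.10,
                      fecundityCaps = c(3L, 6L, 10L),
                      baseLifespan = 10L,
                      nFounders = 30L,
                      founderBlock = 20L,
                      unreducedRate2x = 0.006,
                      unreducedRate4x = 0,
                      triploidGameteMix = c(x = 0.29, "2x" = 0.29,
                                            "3x" = 0.05, aneuploid = 0.37),
                      triploidSeedViability = 0.3,
                      onsetGeneration = 200L,
                      selfingRates = c("2x" = 0, "3x" = 0, "4x" = 0),
                      apomixisRates = c("2x" = 0, "3x" = 0, "4x" = 0),
                      lambdaPollen = 1.6,
                      pollenRadius = 10,
                      lambdaSeed = 1.5,
                      seedRadius = 20,
                      establishmentThreshold = 50L,
                      horizonGenerations = 1000L,
                      segregationSd = 0,
                      uniformE = NA_real_,
                      globalPollen = FALSE,
                      optimumPatches = NULL,
                      ...) {
  p <- list(
    svSd = svSd, limits = limits, limitMultiplier4x = limitMultiplier4x,
    combineRule = combineRule, mortality = mortality,
    fecundityCaps = as.integer(fecundityCaps),
    baseLifespan = as.integer(baseLifespan),
    nFounders = as.integer(nFounders), founderBlock = as.integer(founderBlock),
    unreducedRate2x = unreducedRate2x, unreducedRate4x = unreducedRate4x,
    triploidGameteMix = triploidGameteMix,
    triploidSeedViability = triploidSeedViability,
    onsetGeneration = as.integer(onsetGeneration),
    selfingRates = selfingRates, apomixisRates = apomixisRates,
    lambdaPollen = lambdaPollen, pollenRadius = pollenRadius,
    lambdaSeed = lambdaSeed, seedRadius = seedRadius,
    establishmentThreshold = as.integer(establishmentThreshold),
    horizonGenerations = as.integer(horizonGenerations),
    segregationSd = segregationSd, uniformE = uniformE,
    globalPollen = globalPollen, optimumPatches = optimumPatches
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  new("SimConfig", params = p)
}

#' Update fields of an existing configuration
#'
#' @param config a [SimConfig-class]
#' @param ... fields to replace, by name (see [simConfig()])
#' @export
updateConfig <- function(config, ...) {
  dots <- list(...)
  p <- config@params
  bad <- setdiff(names(dots), names(p))
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  new("SimConfig", params = p)
}

#' Get one configuration parameter
#' @param config a [SimConfig-class]
#' @param name field name
#' @export
configParam <- function(config, name) {
  if (!name %in% names(config@params)) stop("no such parameter: ", name)
  config@params[[name]]
}

#' Classical-comparison (Felber-type) preset
#'
#' Returns a configuration reproducing the assumptions of the deterministic
#' diploid/tetraploid gametic recursion inside the agent-based model:
#' triploid seeds fully inviable, environmental fitness clamped to 1
#' everywhere (equal cytotype fitness, homogeneous environment), and
#' panmictic pollen donation instead of the local neighborhood. With these
#' switches the only structure left relative to the infinite-population
#' recursion is finite census, overlapping generations, and local seed
#' dispersal.
#'
#' @param unreducedRate2x diploid unreduced-gamete rate to run at.
#' @param onsetGeneration generation at which unreduced gametes start; the
#'   default 40 leaves time for the population to saturate the workspace.
#' @param horizonGenerations post-onset horizon.
#' @param ... further overrides passed to [updateConfig()].
#' @export
felberConfig <- function(unreducedRate2x = 0.15, onsetGeneration = 40L,
                         horizonGenerations = 600L, ...) {
  updateConfig(
    simConfig(),
    unreducedRate2x = unreducedRate2x,
    triploidSeedViability = 0,
    uniformE = 1,
    globalPollen = TRUE,
    onsetGeneration = as.integer(onsetGeneration),
    horizonGenerations = as.integer(horizonGenerations),
    ...
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are [simConfig()] fields; unknown keys are an error.
#' Named vectors (e.g. \code{selfingRates}) are given as YAML mappings.
#'
#' @param path YAML file path
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in intersect(names(raw), c("selfingRates", "apomixisRates",
                                     "triploidGameteMix")))
    raw[[nm]] <- unlist(raw[[nm]])
  do.call(simConfig, raw)
}

# Flatten a SimConfig for the C++ engine.
.cfgList <- function(config) {
  p <- config@params
  opt <- p$optimumPatches
  list(
    svSd = as.numeric(p$svSd),
    limits = as.numeric(p$limits),
    k4x = as.numeric(p$limitMultiplier4x),
    combineRule = match(p$combineRule, c("geometric", "product", "min")),
    mortality = as.numeric(p$mortality),
    caps = as.integer(p$fecundityCaps),
    baseLifespan = as.integer(p$baseLifespan),
    p2n2x = as.numeric(p$unreducedRate2x),
    p2n4x = as.numeric(p$unreducedRate4x),
    triMix = as.numeric(p$triploidGameteMix),
    triViab = as.numeric(p$triploidSeedViability),
    onset = as.integer(p$onsetGeneration),
    selfing = as.numeric(p$selfingRates[c("2x", "3x", "4x")]),
    apomixis = as.numeric(p$apomixisRates[c("2x", "3x", "4x")]),
    lambdaPollen = as.numeric(p$lambdaPollen),
    pollenRadius = as.numeric(p$pollenRadius),
    lambdaSeed = as.numeric(p$lambdaSeed),
    seedRadius = as.numeric(p$seedRadius),
    estThreshold = as.integer(p$establishmentThreshold),
    segregationSd = as.numeric(p$segregationSd),
    uniformE = as.numeric(p$uniformE),
    globalPollen = isTRUE(p$globalPollen),
    optimum = if (is.null(opt)) matrix(0, 0, 5) else as.matrix(opt)
  )
}
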