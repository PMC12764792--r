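.envList <- function(grid) {
  list(nx = gridWidth(grid), ny = gridHeight(grid),
       layers = matrix(envLayers(grid), gridWidth(grid) * gridHeight(grid), 5))
}

.emptyCensus <- function() {
  data.frame(generation = integer(), n2x = numeric(), n3x = numeric(),
             n4x = numeric(), sv = numeric())
}

#' Advance a simulation state by one or more generations
#'
#' Executes the generation cycle: one global seasonal draw and a fitness
#' refresh for every plant, background mortality, reproduction (pathway
#' choice, gamete sampling, seed formation, event classification), seed
#' dispersal, simultaneous settlement with patch contention, lineage
#' census/establishment detection, and ageing. Unreduced gamete production
#' is forced off while the generation counter is below the configured onset.
#'
#' @param state a state list from [initializePopulation()] (or a previous
#'   call)
#' @param grid the [EnvironmentGrid-class]
#' @param config a [SimConfig-class]
#' @param nGenerations how many generations to advance
#' @return the advanced state; the per-generation census is attached as
#'   attribute \code{"census"}
#' @export
stepGeneration <- function(state, grid, config = simConfig(),
                           nGenerations = 1L) {
  res <- cpp_simulate(.envList(grid), .cfgList(config), state,
                      as.integer(nGenerations), FALSE, TRUE)
  out <- res$state
  attr(out, "census") <- as.data.frame(res$census)
  out
}

#' Detect newly established polyploidization events
#'
#' Flips any pending event whose living tetraploid descendants reach the
#' establishment threshold to SPE, recording the establishment generation.
#' An event never reverts from SPE. (The engine applies the identical rule
#' every generation; this R version is the reference for testing and for
#' inspecting states.)
#'
#' @param state a simulation state
#' @param threshold establishment census threshold (default from the event
#'   definition: 50)
#' @return the state with updated event outcomes
#' @export
detectEstablishment <- function(state, threshold = 50L) {
  ev <- state$events
  if (!length(ev$type)) return(state)
  tallies <- integer(length(ev$type))
  sel <- state$ploidy == 4L & state$eventId >= 0L
  if (any(sel)) {
    t0 <- table(state$eventId[sel])
    tallies[as.integer(names(t0)) + 1L] <- as.integer(t0)
  }
  flip <- ev$outcome == 0L & tallies >= threshold
  ev$outcome[flip] <- 1L
  ev$genEst[flip] <- state$generation
  state$events <- ev
  state
}

.eventsToDf <- function(ev) {
  data.frame(
    event_id = seq_along(ev$type) - 1L,
    type = c("bilateral", "unilateral")[ev$type],
    founder_ploidy = ev$ploidy,
    generation_formed = ev$genFormed,
    x = ev$x, y = ev$y,
    founder_fitness = ev$founderE,
    founder_relative_fitness = ev$relFitness,
    outcome = c("pending", "SPE", "UPE")[ev$outcome + 1L],
    generation_established = ifelse(ev$genEst < 0, NA_integer_, ev$genEst)
  )
}

#' Run one full replicate
#'
#' Initialises founders on the grid, runs the diploid burn-in (generations
#' up to the unreduced-gamete onset) and the main phase, and stops at
#' tetraploid fixation (4x proportion 1), population extinction, or when
#' the post-onset horizon has elapsed. All pending events are finalised as
#' unsuccessful at stop. Identical (grid, config, seed) reproduce the
#' identical result.
#'
#' @param grid an [EnvironmentGrid-class]; NULL builds the default
#'   calibrated synthetic environment with seed 1
#' @param config a [SimConfig-class]
#' @param seed integer root seed of the replicate
#' @param recordCensus record per-generation cytotype counts
#' @return a [ReplicateResult-class]
#' @export
runReplicate <- function(grid = NULL, config = simConfig(), seed = 1L,
                         recordCensus = FALSE) {
  if (is.null(grid)) grid <- generateSyntheticEnvironment()
  p <- config@params
  maxGen <- p$onsetGeneration + p$horizonGenerations
  res <- withr::with_seed(as.integer(seed), {
    state <- initializePopulation(grid, config)
    cpp_simulate(.envList(grid), .cfgList(config), state, maxGen,
                 TRUE, recordCensus)
  })
  state <- res$state
  ev <- state$events
  pending <- ev$outcome == 0L
  ev$outcome[pending] <- 2L
  state$events <- ev

  spe <- sum(ev$outcome == 1L)
  bil <- sum(ev$type == 1L)
  unil <- sum(ev$type == 2L)
  upe <- bil + unil - spe
  n <- length(state$ploidy)
  prop4 <- if (n == 0L) 0 else mean(state$ploidy == 4L)
  stopReason <- c("fixation", "horizon", "extinct")[res$stopReason]
  guf <- if (identical(stopReason, "fixation"))
    state$generation - p$onsetGeneration else NA_integer_
  gpip <- NA_integer_
  if (spe > 0L) {
    est <- which(ev$outcome == 1L)
    first <- est[which.min(ev$genEst[est])]
    gpip <- ev$genEst[first] - ev$genFormed[first]
  }
  summary <- data.frame(
    spe_count = spe, upe_count = upe,
    bilateral_count = bil, unilateral_count = unil,
    gpip = gpip, guf = guf,
    final_4x_proportion = prop4,
    final_census = n,
    final_generation = state$generation,
    stop_reason = stopReason,
    seed = as.integer(seed)
  )
  census <- if (recordCensus) as.data.frame(res$census) else .emptyCensus()
  new("ReplicateResult", summary = summary, events = .eventsToDf(ev),
      census = census, config = config, seed = as.integer(seed))
}

#' Engine instrumentation counters of a state
#'
#' Cumulative counts of gamete classes drawn, pathway choices, pollen
#' limitation, seed losses by cause, establishments, and the running moments
#' of the seasonal factor. Used by the distribution-recovery tests.
#'
#' @param state a simulation state (as inside [stepGeneration()])
#' @export
engineCounters <- function(state) state$counters
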