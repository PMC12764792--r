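#' Per-variable environmental fitness component
#'
#' Exponential-decay tolerance model: a deviation of the adaptive optimum
#' from the effective variable equal to the tolerance limit halves the
#' component, i.e. \code{2^(-|ia - v| / limit)}. The component is 1 exactly
#' at the optimum and symmetric in its first two arguments.
#'
#' @param ia adaptive optimum for the variable (vectorised)
#' @param v effective variable value on the patch
#' @param limit tolerance half-width (> 0)
#' @return values in (0, 1]
#' @export
fitnessComponent <- function(ia, v, limit) {
  if (any(limit <= 0)) stop("tolerance limit must be positive")
  2^(-abs(ia - v) / limit)
}

#' Combine five fitness components into E
#'
#' @param components numeric(5) in [0,1]
#' @param rule "geometric" (default), "product" or "min"
#' @return scalar E in [0,1]
#' @export
combinedFitness <- function(components, rule = "geometric") {
  if (any(components < 0 | components > 1))
    stop("fitness components must lie in [0,1]")
  switch(rule,
    geometric = prod(components)^(1 / length(components)),
    product = prod(components),
    min = min(components),
    stop("unknown combination rule: ", rule)
  )
}

#' Age-dependent fecundity cap
#'
#' Maximum offspring: 3 for one-year-old plants, 6 for two-year-olds,
#' 10 for older plants.
#'
#' @param age integer cycles (>= 1), vectorised
#' @param caps integer(3) caps at age 1, 2, >= 3
#' @export
ageFecundityCap <- function(age, caps = c(3L, 6L, 10L)) {
  if (any(age < 1)) stop("reproducing plants have age >= 1")
  caps[pmin(age, 3L)]
}

#' Realised fecundity of one plant-cycle
#'
#' A draw from Binomial(cap(age), E): at E = 1 the age cap is attained with
#' certainty, at E = 0 no offspring form, and in between offspring numbers
#' are integer with mean cap x E.
#'
#' @param e environmental fitness component in [0,1] (vectorised)
#' @param age integer cycles (recycled against e)
#' @param caps integer(3) age caps
#' @return integer seed counts
#' @export
realizedFecundity <- function(e, age, caps = c(3L, 6L, 10L)) {
  if (any(e < 0 | e > 1)) stop("e must lie in [0,1]")
  n <- max(length(e), length(age))
  rbinom(n, ageFecundityCap(rep_len(age, n), caps), rep_len(e, n))
}

#' One survival update of a plant
#'
#' The plant dies with the flat per-cycle hazard (default 10\%); otherwise
#' its age increments, and it dies anyway if the incremented age exceeds its
#' lifespan cap (\code{ceiling(baseLifespan x E_at_establishment)}, i.e. 10
#' cycles for a plant established at full fitness).
#'
#' @param age current age in cycles
#' @param maxAge individual lifespan cap
#' @param mortality per-cycle death probability
#' @return list(alive = logical, age = updated age)
#' @export
survivalUpdate <- function(age, maxAge, mortality = 0.10) {
  if (runif(1L) < mortality) return(list(alive = FALSE, age = age))
  age <- age + 1L
  list(alive = age <= maxAge, age = age)
}

#' Lifespan cap at establishment
#'
#' @param e establishment-time fitness in [0,1]
#' @param baseLifespan cap at E = 1 (10 cycles)
#' @export
lifespanCap <- function(e, baseLifespan = 10L) {
  as.integer(ceiling(baseLifespan * e))
}

#' Initialise the founder population
#'
#' Places n diploid founders on distinct free patches inside the central
#' square block of the workspace; each founder's five adaptive-optimum
#' values are copied from its patch, so every founder starts at E = 1 with
#' the full lifespan cap.
#'
#' @param grid an [EnvironmentGrid-class]
#' @param config a [SimConfig-class] (supplies \code{nFounders} and
#'   \code{founderBlock}; override n via \code{n})
#' @param n founder count; defaults to the configured value
#' @return a simulation state, a list understood by [stepGeneration()] and
#'   [runReplicate()]; plant fields are parallel vectors (0-based
#'   coordinates, 5-column trait matrix \code{ia}).
#' @export
initializePopulation <- function(grid, config = simConfig(), n = NULL) {
  p <- config@params
  if (is.null(n)) n <- p$nFounders
  n <- as.integer(n)
  nx <- gridWidth(grid); ny <- gridHeight(grid)
  half <- p$founderBlock %/% 2L
  cx <- nx %/% 2L; cy <- ny %/% 2L
  xs <- max(0L, cx - half):min(nx - 1L, cx + half - 1L)
  ys <- max(0L, cy - half):min(ny - 1L, cy + half - 1L)
  cells <- expand.grid(x = xs, y = ys)
  if (nrow(cells) < n)
    stop("central block has fewer free patches than founders requested")
  pick <- if (n > 0L) cells[sample.int(nrow(cells), n), , drop = FALSE]
          else cells[0, , drop = FALSE]
  ia <- matrix(0, n, 5)
  for (k in seq_len(n))
    ia[k, ] <- envLayers(grid)[pick$x[k] + 1L, pick$y[k] + 1L, ]
  list(
    generation = 0L,
    x = as.integer(pick$x), y = as.integer(pick$y),
    ploidy = rep(2L, n), age = rep(1L, n),
    maxAge = rep(as.integer(p$baseLifespan), n),
    ia = ia,
    eventId = rep(-1L, n),
    e = rep(1, n),
    events = list(type = integer(), ploidy = integer(),
                  genFormed = integer(),
                  x = integer(), y = integer(),
                  founderE = numeric(), relFitness = numeric(),
                  outcome = integer(),
                  genEst = integer()),
    counters = numeric()
  )
}
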