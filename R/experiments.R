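# Deterministic per-replicate seed from (root, family label, level index,
# replicate index); a small multiplicative string hash kept below 2^31.
.replicateSeed <- function(root, family, levelIndex, replicate) {
  h <- as.double(root) %% 2147483647
  for (ch in utf8ToInt(as.character(family)))
    h <- (h * 31 + ch) %% 2147483647
  h <- (h * 131 + levelIndex * 7919) %% 2147483647
  h <- (h * 131 + replicate * 104729) %% 2147483647
  as.integer(max(1, h))
}

#' Define an experiment sweep
#'
#' The five experiment families vary one axis each against the common
#' baseline (natural 0.6\% unreduced gametes, outcrossing, self-sterile,
#' equal tolerance): \describe{
#'   \item{unreduced}{diploid unreduced-gamete rate; levels are proportions
#'     (e.g. 0.006, 0.02, 0.05, 0.10, 0.20).}
#'   \item{selfing}{tetraploid selfing rate (levels 0.10..1).}
#'   \item{apomixis}{tetraploid apomixis rate.}
#'   \item{mixed}{tetraploid apomixis at the level, complemented by selfing
#'     (selfing = 1 - level): a fully non-outcrossing mixed mating system at
#'     every level.}
#'   \item{tolerance}{tetraploid tolerance multiplier k (levels 0.5..2.0);
#'     all plants self-sterile.}
#'   \item{shifted_optimum}{Euclidean shift, in patches, of the 30-patch
#'     tetraploid optimum set from the founder area centroid.}
#' }
#'
#' @param family experiment family name (above)
#' @param levels treatment values, in natural units
#' @param replicates replicates per level
#' @param baseConfig base [SimConfig-class]
#' @param rootSeed root of the deterministic per-replicate seed policy
#' @return list of class \code{"ExperimentDesign"}
#' @export
experimentDesign <- function(family = c("unreduced", "selfing", "apomixis",
                                        "mixed", "tolerance",
                                        "shifted_optimum"),
                             levels, replicates = 30L,
                             baseConfig = simConfig(), rootSeed = 1L) {
  family <- match.arg(family)
  if (!length(levels)) stop("levels must be non-empty")
  if (replicates < 1L) stop("replicates must be >= 1")
  rateFam <- family %in% c("unreduced", "selfing", "apomixis", "mixed")
  if (rateFam && any(levels < 0 | levels > 1))
    stop("rates must lie in [0,1] for family ", family)
  if (family == "tolerance" && any(levels <= 0))
    stop("tolerance multipliers must be positive")
  if (family == "shifted_optimum" && any(levels < 0))
    stop("shift distances must be non-negative")
  structure(list(family = family, levels = levels,
                 replicates = as.integer(replicates),
                 baseConfig = baseConfig, rootSeed = as.integer(rootSeed)),
            class = "ExperimentDesign")
}

.levelConfig <- function(design, level, grid) {
  cfg <- design$baseConfig
  switch(design$family,
    unreduced = updateConfig(cfg, unreducedRate2x = level),
    selfing = updateConfig(cfg,
      selfingRates = c("2x" = 0, "3x" = 0, "4x" = level)),
    apomixis = updateConfig(cfg,
      apomixisRates = c("2x" = 0, "3x" = 0, "4x" = level)),
    mixed = updateConfig(cfg,
      apomixisRates = c("2x" = 0, "3x" = 0, "4x" = level),
      selfingRates = c("2x" = 0, "3x" = 0, "4x" = 1 - level)),
    tolerance = updateConfig(cfg,
      limitMultiplier4x = level,
      selfingRates = c("2x" = 0, "3x" = 0, "4x" = 0),
      apomixisRates = c("2x" = 0, "3x" = 0, "4x" = 0)),
    shifted_optimum = {
      opt <- withr::with_seed(
        .replicateSeed(design$rootSeed, "optimum-set", which(
          design$levels == level)[1], 0L),
        chooseOptimumPatches(grid, level))
      updateConfig(cfg, optimumPatches = opt)
    }
  )
}

#' Run an experiment sweep
#'
#' Runs the configured number of independent replicates at every treatment
#' level, with seeds derived deterministically from the design's root seed.
#'
#' @param design an [experimentDesign()]
#' @param grid the [EnvironmentGrid-class]; NULL builds the default
#'   calibrated synthetic environment
#' @param collectEvents also return the pooled event table (needed for
#'   density maps and founder-fitness contrasts)
#' @return a long data.frame keyed by (family, level, replicate) with the
#'   per-replicate summary columns; when \code{collectEvents} the pooled
#'   event table is attached as attribute \code{"events"}
#' @export
runExperiment <- function(design, grid = NULL, collectEvents = FALSE) {
  stopifnot(inherits(design, "ExperimentDesign"))
  if (is.null(grid)) grid <- generateSyntheticEnvironment()
  rows <- vector("list", length(design$levels) * design$replicates)
  evs <- list()
  k <- 0L
  for (li in seq_along(design$levels)) {
    level <- design$levels[li]
    cfg <- .levelConfig(design, level, grid)
    for (r in seq_len(design$replicates)) {
      seed <- .replicateSeed(design$rootSeed, design$family, li, r)
      rep <- runReplicate(grid, cfg, seed = seed)
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(family = design$family, level = level, replicate = r),
        replicateSummary(rep))
      if (collectEvents) {
        e <- eventRecords(rep)
        if (nrow(e))
          evs[[length(evs) + 1L]] <- cbind(
            data.frame(family = design$family, level = level,
                       replicate = r), e)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (collectEvents)
    attr(out, "events") <- if (length(evs)) do.call(rbind, evs) else
      data.frame()
  out
}

#' Per-treatment summary statistics
#'
#' Mean and standard deviation per level for each response; the
#' establishment and fixation waiting times (GPIP, GuF) are averaged over
#' the replicates where they are defined and reported NA when never
#' defined.
#'
#' @param table long table from [runExperiment()]
#' @return data.frame, one row per level
#' @export
summarizeTreatments <- function(table) {
  if (!nrow(table)) stop("empty replicate table")
  resp <- c("spe_count", "upe_count", "bilateral_count", "unilateral_count",
            "final_4x_proportion")
  lv <- sort(unique(table$level))
  out <- lapply(lv, function(l) {
    sub <- table[table$level == l, , drop = FALSE]
    row <- data.frame(level = l, n = nrow(sub))
    for (v in resp) {
      row[[paste0(v, "_mean")]] <- mean(sub[[v]])
      row[[paste0(v, "_sd")]] <- sd(sub[[v]])
    }
    for (v in c("gpip", "guf")) {
      ok <- !is.na(sub[[v]])
      row[[paste0(v, "_mean")]] <- if (any(ok)) mean(sub[[v]][ok]) else
        NA_real_
      row[[paste0(v, "_n")]] <- sum(ok)
    }
    row
  })
  do.call(rbind, out)
}

# Compact letter display by insert-and-absorb on the significance matrix:
# start from one letter covering all groups, split a letter for every
# significant pair it still joins, absorb redundant subsets, then label
# letters in order of the best group mean they contain.
.compactLetters <- function(means, sig) {
  g <- length(means)
  cols <- list(rep(TRUE, g))
  for (i in seq_len(g - 1L)) for (j in seq.int(i + 1L, g)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      cl <- cols[[ci]]
      if (cl[i] && cl[j]) {
        a <- cl; a[i] <- FALSE
        b <- cl; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci == cj || !keep[ci] || !keep[cj]) next
      if (all(cols[[ci]] <= cols[[cj]]) && any(cols[[cj]] & !cols[[ci]]))
        keep[ci] <- FALSE
      else if (ci < cj && identical(cols[[ci]], cols[[cj]]))
        keep[cj] <- FALSE
    }
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, function(cl) max(means[cl]), numeric(1)),
               decreasing = TRUE)
  cols <- cols[ord]
  lab <- rep("", g)
  for (ci in seq_along(cols))
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], letters[ci])
  lab
}

#' Compare treatment levels (ANOVA + Tukey HSD letters)
#'
#' One-way analysis of variance of the response across levels followed by
#' Tukey's honest significant difference over all level pairs at the given
#' alpha; levels are then labelled with a compact letter display (levels
#' sharing a letter are not significantly different; the level with the
#' highest mean gets "a"). Degenerate inputs with zero variance everywhere
#' and equal means share a single letter.
#'
#' @param table long table from [runExperiment()]
#' @param response response column name (e.g. "spe_count")
#' @param alpha pairwise significance level (0.01)
#' @return data.frame with level, mean, sd and letter group; the ANOVA F
#'   statistic and p value are in attributes \code{"F"} and \code{"p"}
#' @export
compareTreatments <- function(table, response = "spe_count", alpha = 0.01) {
  lv <- sort(unique(table$level))
  if (length(lv) < 2L) stop("need at least two levels")
  y <- table[[response]]
  f <- factor(table$level, levels = lv)
  if (any(tapply(y, f, length) < 2L)) stop("need >= 2 replicates per level")
  means <- as.numeric(tapply(y, f, mean))
  sds <- as.numeric(tapply(y, f, sd))
  g <- length(lv)
  sig <- matrix(FALSE, g, g)
  fit <- aov(y ~ f)
  an <- summary(fit)[[1]]
  Fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  if (is.finite(an[["Mean Sq"]][2]) && an[["Mean Sq"]][2] > 0) {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$f
    pr <- tk[, "p adj"]
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (k in seq_along(pr)) {
      i <- match(nm[[k]][1], as.character(lv))
      j <- match(nm[[k]][2], as.character(lv))
      if (!is.na(i) && !is.na(j) && is.finite(pr[k]) && pr[k] < alpha)
        sig[i, j] <- sig[j, i] <- TRUE
    }
  } else {
    # no residual variance: distinct means are trivially separated
    for (i in seq_len(g - 1L)) for (j in seq.int(i + 1L, g))
      if (means[i] != means[j]) sig[i, j] <- sig[j, i] <- TRUE
  }
  out <- data.frame(level = lv, mean = means, sd = sds,
                    letters = .compactLetters(means, sig))
  attr(out, "F") <- Fstat
  attr(out, "p") <- pval
  out
}

#' Density map of first successful establishment sites
#'
#' Accumulates, over replicates, the location of the founding individual of
#' each replicate's first successful polyploidization event onto a count
#' grid. The maximal diploid range (patches suitable for the founder-mean
#' genotype) can be overlaid downstream via [suitabilityMap()].
#'
#' @param events pooled event table from
#'   \code{runExperiment(..., collectEvents = TRUE)} (needs columns
#'   replicate, outcome, generation_established, x, y); an empty table
#'   yields an all-zero grid
#' @param dims integer(2) grid dimensions
#' @param firstOnly count only the first SPE per replicate (the mapped
#'   statistic); FALSE counts every SPE founder
#' @return integer width x height count matrix
#' @export
speDensityMap <- function(events, dims = c(100L, 100L), firstOnly = TRUE) {
  m <- matrix(0L, dims[1], dims[2])
  if (!NROW(events)) return(m)
  spe <- events[events$outcome == "SPE", , drop = FALSE]
  if (!nrow(spe)) return(m)
  if (firstOnly) {
    if (is.null(spe$replicate)) spe$replicate <- 1L
    if (is.null(spe$family)) spe$family <- "run"
    if (is.null(spe$level)) spe$level <- 0
    key <- interaction(spe$family, spe$level, spe$replicate, drop = TRUE)
    pick <- unlist(lapply(split(seq_len(nrow(spe)), key), function(ix)
      ix[which.min(spe$generation_established[ix])]))
    spe <- spe[pick, , drop = FALSE]
  }
  for (k in seq_len(nrow(spe))) {
    i <- spe$x[k] + 1L; j <- spe$y[k] + 1L
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Establishment efficiency per treatment level
#'
#' The mean final tetraploid proportion divided by the mean number of
#' successful polyploidization events: how much fixation each successful
#' event buys. Undefined (NA) for levels with no successful events.
#'
#' @param summaries output of [summarizeTreatments()]
#' @return data.frame with level and efficiency
#' @export
establishmentEfficiency <- function(summaries) {
  eff <- ifelse(summaries$spe_count_mean > 0,
                summaries$final_4x_proportion_mean / summaries$spe_count_mean,
                NA_real_)
  data.frame(level = summaries$level, efficiency = eff)
}
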