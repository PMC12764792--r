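test_that("replicates are bitwise reproducible and configs validate", {
  g <- smallGrid()
  cfg <- fastConfig(unreducedRate2x = 0.1)
  r1 <- runReplicate(g, cfg, seed = 99L)
  r2 <- runReplicate(g, cfg, seed = 99L)
  expect_identical(replicateSummary(r1), replicateSummary(r2))
  expect_identical(eventRecords(r1), eventRecords(r2))
  r3 <- runReplicate(g, cfg, seed = 100L)
  expect_false(identical(replicateSummary(r1), replicateSummary(r3)))
  expect_error(simConfig(unreducedRate2x = 1.5), "0,1")
  expect_error(simConfig(limits = c(1, 1, 1, 0, 1)), "positive")
})

test_that("an empty population only advances the generation counter", {
  g <- smallGrid()
  st <- initializePopulation(g, fastConfig(), n = 0)
  st2 <- stepGeneration(st, g, fastConfig(), nGenerations = 3L)
  expect_identical(st2$generation, 3L)
  expect_identical(length(st2$x), 0L)
  r <- runReplicate(g, fastConfig(nFounders = 0L), seed = 1L)
  s <- replicateSummary(r)
  expect_identical(s$spe_count, 0L)
  expect_identical(s$stop_reason, "extinct")
})

test_that("no polyploidization events are logged before the onset", {
  g <- smallGrid()
  cfg <- simConfig(unreducedRate2x = 0.2, onsetGeneration = 500L,
                   horizonGenerations = 0L)
  st <- withr::with_seed(13, initializePopulation(g, cfg))
  st <- withr::with_seed(14, stepGeneration(st, g, cfg, nGenerations = 150L))
  expect_identical(length(st$events$type), 0L)
  cnt <- engineCounters(st)
  expect_identical(unname(cnt["gamete_2x_unreduced"]), 0)
  expect_gt(cnt["gamete_2x_reduced"], 0)
})

test_that("ploidy closure holds: only 2x, 3x, 4x plants ever live", {
  g <- smallGrid()
  cfg <- fastConfig(unreducedRate2x = 0.2)
  st <- withr::with_seed(15, initializePopulation(g, cfg))
  st <- withr::with_seed(16, stepGeneration(st, g, cfg, nGenerations = 60L))
  expect_true(all(st$ploidy %in% c(2L, 3L, 4L)))
  expect_gt(length(st$events$type), 0L)
})

test_that("the seasonal factor is global per generation with the stated law", {
  g <- smallGrid()
  cfg <- fastConfig()
  st <- withr::with_seed(17, initializePopulation(g, cfg))
  st <- withr::with_seed(18, stepGeneration(st, g, cfg, nGenerations = 40L))
  cen <- attr(st, "census")
  # one sv per generation, Gaussian around 1 at sd 1e-3
  expect_identical(nrow(cen), 40L)
  expect_lt(max(abs(cen$sv - 1)), 6e-3)
  cnt <- engineCounters(st)
  expect_identical(unname(cnt["sv_n"]), 40)
  expect_lt(abs(cnt["sv_sum"] / cnt["sv_n"] - 1), 1e-3)
})

test_that("establishment detection flips pending events at the threshold", {
  base <- initializePopulation(smallGrid(), fastConfig(), n = 0)
  mk <- function(n4) {
    st <- base
    st$generation <- 77L
    st$ploidy <- rep(4L, n4)
    st$eventId <- rep(0L, n4)
    st$x <- seq_len(n4); st$y <- rep(1L, n4)
    st$events <- list(type = 1L, genFormed = 60L, x = 1L, y = 1L,
                      founderE = 0.9, outcome = 0L, genEst = -1L)
    st
  }
  below <- detectEstablishment(mk(49L))
  expect_identical(below$events$outcome, 0L)
  at <- detectEstablishment(mk(50L))
  expect_identical(at$events$outcome, 1L)
  expect_identical(at$events$genEst, 77L)
  # never reverts once established
  at$ploidy <- at$ploidy[1:3]; at$eventId <- at$eventId[1:3]
  again <- detectEstablishment(at)
  expect_identical(again$events$outcome, 1L)
})

test_that("summary identities hold: SPE + UPE = bilateral + unilateral", {
  g <- smallGrid()
  for (s in 1:4) {
    r <- runReplicate(g, fastConfig(unreducedRate2x = 0.15), seed = 200L + s)
    x <- replicateSummary(r)
    expect_identical(x$spe_count + x$upe_count,
                     x$bilateral_count + x$unilateral_count)
    ev <- eventRecords(r)
    expect_identical(nrow(ev), x$bilateral_count + x$unilateral_count)
    expect_false(any(ev$outcome == "pending"))
    expect_true(all(ev$founder_fitness >= 0.5 | is.na(ev$founder_fitness)))
    expect_gte(x$final_4x_proportion, 0)
    expect_lte(x$final_4x_proportion, 1)
    if (x$stop_reason == "fixation") expect_false(is.na(x$guf))
  }
})

test_that("with no unreduced gametes nothing polyploid ever forms", {
  g <- smallGrid()
  r <- runReplicate(g, fastConfig(unreducedRate2x = 0), seed = 31L)
  x <- replicateSummary(r)
  expect_identical(x$spe_count + x$upe_count, 0L)
  expect_identical(x$final_4x_proportion, 0)
  expect_identical(x$stop_reason, "horizon")
})

test_that("engine distributions match the configured rates", {
  g <- uniformGrid(20L)
  cfg <- simConfig(unreducedRate2x = 0.2, onsetGeneration = 1L,
                   horizonGenerations = 60L, uniformE = 1,
                   selfingRates = c("2x" = 0.3, "3x" = 0, "4x" = 0),
                   apomixisRates = c("2x" = 0.2, "3x" = 0, "4x" = 0),
                   triploidSeedViability = 0)
  st <- withr::with_seed(19, initializePopulation(g, cfg))
  st <- withr::with_seed(20, stepGeneration(st, g, cfg, nGenerations = 30L))
  cnt <- engineCounters(st)
  un <- cnt["gamete_2x_unreduced"] / (cnt["gamete_2x_unreduced"] +
                                      cnt["gamete_2x_reduced"])
  expect_lt(abs(un - 0.2), 0.02)
  tot <- cnt["pathway_outcross"] + cnt["pathway_self"] +
    cnt["pathway_apomixis"]
  expect_lt(abs(cnt["pathway_self"] / tot - 0.3), 0.03)
  expect_lt(abs(cnt["pathway_apomixis"] / tot - 0.2), 0.03)
})

test_that("YAML run configurations round-trip through the reader", {
  path <- file.path(tempdir(), "run.yaml")
  writeLines(c(
    "unreducedRate2x: 0.05",
    "triploidSeedViability: 0.25",
    "selfingRates:",
    "  2x: 0.0", "  3x: 0.0", "  4x: 0.75"), path)
  cfg <- readConfig(path)
  expect_equal(configParam(cfg, "unreducedRate2x"), 0.05)
  expect_equal(configParam(cfg, "triploidSeedViability"), 0.25)
  expect_equal(unname(configParam(cfg, "selfingRates")["4x"]), 0.75)
  # unknown keys are rejected
  writeLines("notAKnob: 1", path)
  expect_error(readConfig(path), "unknown")
})
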