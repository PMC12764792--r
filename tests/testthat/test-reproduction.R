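test_that("gamete class distributions follow cytotype and onset rules", {
  cfg <- simConfig(unreducedRate2x = 0.2)
  d2 <- gameteClassDistribution(2, cfg)
  expect_equal(d2$prob[d2$klass == "unreduced"], 0.2)
  # before the onset generation diploids emit no unreduced gametes
  d2pre <- gameteClassDistribution(2, cfg, generation = 150)
  expect_equal(d2pre$prob[d2pre$klass == "unreduced"], 0)
  d4 <- gameteClassDistribution(4, simConfig(unreducedRate4x = 0))
  expect_identical(d4$prob, c(1, 0))
  d3 <- gameteClassDistribution(3, cfg)
  expect_equal(sum(d3$prob), 1)
  expect_error(gameteClassDistribution(5, cfg), "ploidy")

  # sampled frequencies converge to the configured distribution
  withr::with_seed(21, {
    s <- sampleGametes(10000, 2, cfg)
    expect_lt(abs(mean(s$klass == "unreduced") - 0.2), 0.012)
    s3 <- sampleGametes(10000, 3, cfg)
    d3 <- gameteClassDistribution(3, cfg)
    expProb <- tapply(d3$prob, d3$klass, sum)
    tab <- table(s3$klass)[names(expProb)]
    chi <- suppressWarnings(
      chisq.test(as.numeric(tab), p = as.numeric(expProb)))
    expect_gt(chi$p.value, 1e-4)
  })
})

test_that("pathway choice matches the configured mating rates", {
  withr::with_seed(31, {
    cfg <- simConfig(selfingRates = c("2x" = 0, "3x" = 0, "4x" = 0.5),
                     apomixisRates = c("2x" = 0, "3x" = 0, "4x" = 0.5))
    pw <- choosePathway(10000, 4, cfg)
    expect_lt(abs(mean(pw == "self") - 0.5), 0.015)
    expect_lt(abs(mean(pw == "apomixis") - 0.5), 0.015)
    expect_true(all(choosePathway(500, 4,
      simConfig(selfingRates = c("2x" = 0, "3x" = 0, "4x" = 1))) == "self"))
    expect_true(all(choosePathway(500, 2, simConfig()) == "outcross"))
  })
  expect_error(simConfig(selfingRates = c("2x" = 0.6, "3x" = 0, "4x" = 0),
                         apomixisRates = c("2x" = 0.6, "3x" = 0, "4x" = 0)))
})

test_that("pollen donors are distance-weighted and pollen limitation bites", {
  cfg <- simConfig()
  # lone candidate is always chosen
  expect_identical(selectPollenDonor(1, c(0, 1), c(0, 0), cfg), 2L)
  # isolated mother: no donor
  expect_identical(selectPollenDonor(1, c(0, 50), c(0, 50), cfg),
                   NA_integer_)
  # near vs far candidate: odds exp(5/1.6) ~ 22.8 : 1
  withr::with_seed(41, {
    picks <- replicate(4000,
      selectPollenDonor(1, c(0, 1, 6), c(0, 0, 0), cfg))
    odds <- sum(picks == 2L) / sum(picks == 3L)
    expect_gt(odds, 22.8 * 0.7)
    expect_lt(odds, 22.8 * 1.4)
  })
})

test_that("seed ploidy closure and event classification follow the gametes", {
  red1 <- list(dosage = 1, klass = "reduced")
  red2 <- list(dosage = 2, klass = "reduced")
  un2 <- list(dosage = 2, klass = "unreduced")
  un3 <- list(dosage = 3, klass = "unreduced")
  un4 <- list(dosage = 4, klass = "unreduced")
  aneu <- list(dosage = NA, klass = "aneuploid")

  expect_identical(seedPloidy(red1, red1), 2L)
  expect_identical(seedPloidy(un2, red1), 3L)   # triploid bridge
  expect_identical(seedPloidy(un2, un2), 4L)
  expect_identical(seedPloidy(un3, red1), 4L)
  expect_true(is.na(seedPloidy(aneu, red1)))    # aneuploid inviable
  expect_true(is.na(seedPloidy(un4, red1)))     # > 4x inviable
  expect_true(is.na(seedPloidy(un2, un3)))      # 5x inviable

  expect_identical(classifyPolyploidization(un2, un2), "bilateral")
  expect_identical(classifyPolyploidization(un2, red1), "unilateral")
  expect_identical(classifyPolyploidization(red1, red1), "none")
  # two reduced 2x gametes make a tetraploid without an unreduced event
  expect_identical(classifyPolyploidization(red2, red2), "none")
})

test_that("trait inheritance is mid-parent for sex, clonal for apomixis", {
  m <- c(10, 2, 30, 4, 50); f <- c(20, 4, 10, 4, 10)
  expect_identical(inheritAdaptivity("apomixis", m), m)
  expect_identical(inheritAdaptivity("outcross", m, f), (m + f) / 2)
  expect_identical(inheritAdaptivity("self", m, m), m)
  expect_error(inheritAdaptivity("outcross", m), "father")
  withr::with_seed(5, {
    kid <- inheritAdaptivity("outcross", m, f, segregationSd = 0.1)
    expect_false(identical(kid, (m + f) / 2))
    expect_lt(max(abs(kid - (m + f) / 2)), 1)
  })
})

test_that("shifted-optimum patch sets sit at the requested distance", {
  g <- defaultGridCached()
  withr::with_seed(6, {
    opt <- chooseOptimumPatches(g, 20)
    expect_identical(dim(opt), c(30L, 5L))
    d <- sqrt((attr(opt, "x") - 50)^2 + (attr(opt, "y") - 50)^2)
    expect_true(all(abs(d - 20) <= 2))
    # matched plant has E = 1 on its optimum patch
    k <- 7L
    v <- envLayers(g)[attr(opt, "x")[k] + 1, attr(opt, "y")[k] + 1, ]
    expect_equal(combinedFitness(fitnessComponent(opt[k, ], v,
      configParam(simConfig(), "limits"))), 1)
    # shift 0 draws from the founder neighbourhood itself
    opt0 <- chooseOptimumPatches(g, 0)
    d0 <- sqrt((attr(opt0, "x") - 50)^2 + (attr(opt0, "y") - 50)^2)
    expect_true(all(d0 <= 3.5))
  })
  expect_error(chooseOptimumPatches(g, 20, n = 100000L), "fewer")
})
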