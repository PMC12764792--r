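test_that("tolerance fitness component has the exact closed form", {
  expect_identical(fitnessComponent(10, 10, 2), 1)
  expect_equal(fitnessComponent(12, 10, 2), 0.5)
  expect_equal(fitnessComponent(14, 10, 2), 0.25)
  expect_error(fitnessComponent(1, 1, 0), "positive")

  # symmetry and monotonicity in the tolerance limit
  withr::with_seed(9, {
    ia <- runif(50, -5, 5); v <- runif(50, -5, 5); L <- runif(50, 0.1, 3)
    expect_equal(fitnessComponent(ia, v, L), fitnessComponent(v, ia, L))
    expect_true(all(fitnessComponent(ia, v, L * 2) >=
                    fitnessComponent(ia, v, L)))
    d <- abs(ia - v)
    ord <- order(d)
    expect_true(all(diff(fitnessComponent(ia, v, 1)[ord]) <= 1e-12))
  })
})

test_that("component combination rules behave as documented", {
  expect_identical(combinedFitness(rep(1, 5)), 1)
  expect_identical(combinedFitness(c(1, 1, 0, 1, 1)), 0)
  expect_equal(combinedFitness(c(1, 1, 1, 1, 0.5)), 0.5^(1 / 5))
  expect_equal(combinedFitness(c(0.9, 0.8, 1, 1, 1), rule = "min"), 0.8)
  expect_equal(combinedFitness(c(0.5, 0.5, 1, 1, 1), rule = "product"), 0.25)
  expect_error(combinedFitness(c(1, 1, 1, 1, 1.2)), "components")
})

test_that("age caps and realised fecundity follow the age schedule", {
  expect_identical(ageFecundityCap(c(1, 2, 3, 7, 10)),
                   c(3L, 6L, 10L, 10L, 10L))
  expect_error(ageFecundityCap(0), "age")
  withr::with_seed(4, {
    expect_true(all(realizedFecundity(rep(1, 200), 7) == 10L))
    expect_true(all(realizedFecundity(rep(0, 200), 3) == 0L))
    draws <- realizedFecundity(rep(0.5, 10000), 1)
    expect_lt(abs(mean(draws) - 1.5), 0.05)
    # stochastic dominance in age at fixed e
    m <- sapply(1:3, function(a) mean(realizedFecundity(rep(0.7, 4000), a)))
    expect_true(all(diff(m) > 0))
  })
})

test_that("survival combines the flat hazard with the lifespan cap", {
  withr::with_seed(8, {
    outcomes <- replicate(10000, survivalUpdate(3L, 10L)$alive)
    expect_lt(abs(mean(!outcomes) - 0.10), 0.01)
    # at the cap, death is certain even when the hazard is survived
    atCap <- replicate(200, survivalUpdate(10L, 10L)$alive)
    expect_false(any(atCap))
  })
  expect_identical(lifespanCap(1), 10L)
  expect_identical(lifespanCap(0.61), 7L)
})

test_that("founders start at the patch optimum with E = 1", {
  g <- smallGrid()
  st <- withr::with_seed(3, initializePopulation(g, simConfig()))
  expect_identical(length(st$x), 30L)
  expect_true(all(st$ploidy == 2L))
  expect_true(all(st$e == 1))
  expect_false(any(duplicated(cbind(st$x, st$y))))
  for (k in seq_along(st$x))
    expect_equal(st$ia[k, ], envLayers(g)[st$x[k] + 1, st$y[k] + 1, ])
  # founders sit in the central block
  expect_true(all(abs(st$x - gridWidth(g) %/% 2) <= 10))
  # degenerate: zero founders
  st0 <- initializePopulation(g, simConfig(), n = 0)
  expect_identical(length(st0$x), 0L)
  expect_error(initializePopulation(g, simConfig(founderBlock = 2L)),
               "fewer")
})
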