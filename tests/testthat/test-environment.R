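test_that("synthetic generation is deterministic and validates its spec", {
  g1 <- smallGrid(seed = 5L)
  g2 <- smallGrid(seed = 5L)
  expect_identical(envLayers(g1), envLayers(g2))
  g3 <- smallGrid(seed = 6L)
  expect_false(identical(envLayers(g1), envLayers(g3)))
  expect_error(syntheticEnvSpec(corLengths = c(0, 1, 1, 1, 1)),
               "correlation")
  expect_error(syntheticEnvSpec(amplitudes = c(-1, 0, 0, 0, 0)),
               "amplitude")
})

test_that("zero-amplitude layers are uniform and everywhere suitable", {
  g <- uniformGrid(12L)
  for (i in 1:5)
    expect_equal(diff(range(envLayers(g)[, , i])), 0)
  ia <- envLayers(g)[1, 1, ]
  expect_true(all(suitabilityMap(g, ia, simConfig())))
})

test_that("bioclim layers are near-uniform relative to soil layers", {
  g <- defaultGridCached()
  rel <- apply(envLayers(g), 3, function(m) sd(m) / mean(m))
  expect_lt(max(rel[1:3]), 0.01)        # bioclim: < 1% relative spread
  expect_gt(min(rel[4:5]), 0.02)        # soil: visibly patchy
})

test_that("suitable area for the founder genotypes restricts the workspace", {
  g <- defaultGridCached()
  cfg <- simConfig()
  range2x <- founderRangeMap(g, cfg)
  frac <- mean(range2x)
  expect_gt(frac, 0.05)
  expect_lt(frac, 1)
  # any single founder genotype occupies a strict subset of the range
  ia <- envLayers(g)[51, 51, ]
  expect_lt(mean(suitabilityMap(g, ia, cfg)), frac)
  # a doubled tolerance multiplier widens the tetraploid range
  wide <- founderRangeMap(g, updateConfig(cfg, limitMultiplier4x = 2),
                          ploidy = 4L)
  expect_gt(mean(wide), frac)
})

test_that("seasonal factor recovers its Gaussian law and only scales V1-V3", {
  withr::with_seed(42, {
    sv <- replicate(10000, drawSeasonalFactor())
    expect_lt(abs(mean(sv) - 1), 1e-4)
    expect_lt(abs(sd(sv) - 1e-3), 1e-4)
    # 4-sigma band: relative perturbation of a bioclim layer stays below 0.4%
    expect_gte(mean(abs(sv - 1) <= 0.004), 0.9995)
  })
  g <- uniformGrid(5L)
  expect_equal(effectiveVariable(g, c(2, 3), 2, sv = 0.999),
               envLayers(g)[3, 4, 2] * 0.999)
  expect_equal(effectiveVariable(g, c(2, 3), 4, sv = 1.003),
               envLayers(g)[3, 4, 4])  # soil unmodified
  expect_equal(effectiveVariable(g, c(0, 0), 1, sv = 1),
               envLayers(g)[1, 1, 1])
  expect_error(effectiveVariable(g, c(0, 0), 6), "layer index")
  expect_identical(withr::with_seed(1, drawSeasonalFactor(sd = 0)), 1)
})

test_that("CSV round trip and bilinear resampling behave as interpolation", {
  g <- smallGrid(seed = 2L, n = 12L)
  pre <- file.path(tempdir(), "env")
  paths <- writeEnvironmentCsv(g, pre)
  g2 <- loadRasterEnvironment(paths, target = c(12L, 12L))
  expect_equal(envLayers(g2), envLayers(g), tolerance = 1e-8,
               ignore_attr = TRUE)

  # constant raster stays constant at any resolution
  cpath <- file.path(tempdir(), "const.csv")
  write.table(matrix(7, 5, 5), cpath, sep = ",", row.names = FALSE,
              col.names = FALSE)
  gc5 <- loadRasterEnvironment(rep(cpath, 5), target = c(17L, 9L))
  expect_true(all(envLayers(gc5) == 7))

  # 2x2 with rows 0,0 / 10,10 upsampled to 4x4: linear interior rows
  m <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  tpath <- file.path(tempdir(), "tiny.csv")
  write.table(m, tpath, sep = ",", row.names = FALSE, col.names = FALSE)
  gt <- loadRasterEnvironment(rep(tpath, 5), target = c(4L, 4L))
  # top file row maps to the top of the map; y runs bottom-up in the array
  col <- envLayers(gt)[1, , 1]
  expect_equal(col, c(10, 7.5, 2.5, 0))
  expect_error(loadRasterEnvironment(rep(tpath, 5),
               window = list(rowMin = 1, rowMax = 3, colMin = 1, colMax = 2)),
               "window")
  expect_error(loadRasterEnvironment(rep("/nonexistent/x.csv", 5)),
               "not found")
})
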