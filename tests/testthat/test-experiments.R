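test_that("experiment sweeps produce tidy, reproducible tables", {
  g <- smallGrid()
  des <- experimentDesign("unreduced", levels = c(0.05, 0.2),
                          replicates = 3L, baseConfig = fastConfig(),
                          rootSeed = 4L)
  tab <- runExperiment(des, g)
  expect_identical(nrow(tab), 6L)
  expect_true(all(c("family", "level", "replicate", "spe_count",
                    "final_4x_proportion") %in% names(tab)))
  tab2 <- runExperiment(des, g)
  expect_identical(tab, tab2)
  expect_error(experimentDesign("selfing", levels = c(0.5, 1.5)), "rates")
  expect_error(experimentDesign("unreduced", levels = numeric()), "levels")
})

test_that("treatment summaries follow the closed forms and report na", {
  tab <- data.frame(
    family = "unreduced", level = rep(c(1, 2), each = 3),
    replicate = rep(1:3, 2),
    spe_count = c(1, 2, 3, 0, 0, 0),
    upe_count = c(5, 5, 5, 7, 8, 9),
    bilateral_count = c(3, 3, 4, 3, 4, 4),
    unilateral_count = c(3, 4, 4, 4, 4, 5),
    gpip = c(10, NA, 14, NA, NA, NA),
    guf = c(NA, NA, NA, NA, NA, NA),
    final_4x_proportion = c(1, 1, 0.5, 0, 0, 0))
  s <- summarizeTreatments(tab)
  expect_equal(s$spe_count_mean, c(2, 0))
  expect_equal(s$spe_count_sd, c(1, 0))
  expect_equal(s$gpip_mean, c(12, NA_real_))
  expect_identical(s$gpip_n, c(2L, 0L))
  expect_true(all(is.na(s$guf_mean)))       # never fixed: reported absent
})

test_that("ANOVA + Tukey letters separate what should be separated", {
  withr::with_seed(61, {
    tab <- data.frame(
      level = rep(c(1, 2, 3), each = 8),
      spe_count = c(rnorm(8, 0, 0.05), rnorm(8, 0, 0.05),
                    rnorm(8, 10, 0.05)))
    cl <- compareTreatments(tab, "spe_count", alpha = 0.01)
    expect_identical(cl$letters[cl$level == 3], "a")
    expect_identical(cl$letters[cl$level == 1], cl$letters[cl$level == 2])
    expect_false(cl$letters[cl$level == 3] %in%
                 cl$letters[cl$level %in% c(1, 2)])
  })
  # hand-computed one-way ANOVA F on a tiny fixture
  tab2 <- data.frame(level = rep(1:3, each = 3),
                     y = c(1, 2, 3, 4, 5, 6, 10, 11, 12))
  # groups means 2,5,11; grand 6; SSB = 3*(16+1+25)=126; SSW = 6; F = 63/1
  cl2 <- compareTreatments(tab2, "y", alpha = 0.01)
  expect_equal(attr(cl2, "F"), 63, tolerance = 1e-6)
  # zero variance, equal means: a single shared letter
  tab3 <- data.frame(level = rep(1:2, each = 3), y = rep(5, 6))
  cl3 <- compareTreatments(tab3, "y")
  expect_identical(unique(cl3$letters), "a")
})

test_that("density maps conserve event mass and efficiency is a ratio", {
  ev <- data.frame(
    family = "tolerance", level = 2, replicate = c(1, 1, 2, 3),
    outcome = c("SPE", "SPE", "UPE", "SPE"),
    generation_established = c(210, 250, NA, 230),
    x = c(5, 6, 7, 8), y = c(5, 6, 7, 8))
  m <- speDensityMap(ev, dims = c(10L, 10L))
  expect_identical(sum(m), 2L)              # first SPE per replicate only
  expect_identical(m[6, 6], 1L)             # the earlier of replicate 1
  mAll <- speDensityMap(ev, dims = c(10L, 10L), firstOnly = FALSE)
  expect_identical(sum(mAll), 3L)
  expect_identical(sum(speDensityMap(ev[0, ], dims = c(10L, 10L))), 0L)

  s <- data.frame(level = c(1, 2), spe_count_mean = c(2, 0),
                  final_4x_proportion_mean = c(1, 0))
  eff <- establishmentEfficiency(s)
  expect_equal(eff$efficiency, c(0.5, NA))
})
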