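# Shared fixtures: tiny environments and configs used across the suite.

# A small, fast workspace (same generator, fewer patches) for engine tests.
smallGrid <- function(seed = 11L, n = 40L) {
  generateSyntheticEnvironment(
    syntheticEnvSpec(width = n, height = n,
                     corLengths = c(24, 24, 24, 8, 8)),
    seed = seed)
}

# Perfectly uniform workspace: every patch identical, founders at E = 1.
uniformGrid <- function(n = 30L) {
  generateSyntheticEnvironment(
    syntheticEnvSpec(width = n, height = n, amplitudes = rep(0, 5),
                     trends = rep(0, 5)),
    seed = 1L)
}

# The calibrated full-size environment (built once per test run).
defaultGridCached <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- generateSyntheticEnvironment()
    g
  }
})

fastConfig <- function(...) {
  simConfig(onsetGeneration = 20L, horizonGenerations = 60L, ...)
}
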