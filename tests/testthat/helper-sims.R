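## Shared simulation fixtures, built lazily and cached so the heavier
## datasets are generated once per test run.

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(name, cfg) {
  if (is.null(.simCache[[name]]))
    .simCache[[name]] <- simulateDataset(cfg)
  .simCache[[name]]
}

## standard-size dataset at the default study conditions with a
## deliberately misestimated error model (K = 1.2, g = 0.03)
bigSimConfig <- function(seed = 101L)
  simulationConfig(noise = noiseModel(gTrue = 0.03, KTrue = 1.2),
                   seed = seed)

bigSim <- function() cachedSim("big", bigSimConfig())

bigMergedMmm <- function() {
  if (is.null(.simCache[["bigMergedMmm"]]))
    .simCache[["bigMergedMmm"]] <-
      mergeObservations(bigSim()$observations, laueClass("mmm"))
  .simCache[["bigMergedMmm"]]
}

## dataset at the resolution the study's crystals actually reach
## (1.7 A), for the Wilson-B recovery checks
wilsonSimConfig <- function(seed = 103L)
  simulationConfig(dMin = 1.7, seed = seed)

wilsonMergedMmm <- function() {
  if (is.null(.simCache[["wilsonMergedMmm"]]))
    .simCache[["wilsonMergedMmm"]] <- mergeObservations(
      cachedSim("wilson", wilsonSimConfig())$observations,
      laueClass("mmm"))
  .simCache[["wilsonMergedMmm"]]
}

## ice-contaminated dataset at the default redundancy
iceSimConfig <- function(seed = 102L)
  simulationConfig(iceWindows = defaultIceWindows(), seed = seed)

iceSim <- function() cachedSim("ice", iceSimConfig())

## small fast dataset for property loops
smallSimConfig <- function(seed, ...)
  simulationConfig(cell = unitCell(40, 40, 30), dMin = 2.8, dMax = 20,
                   seed = seed, ...)

## fixture header paths
raxisHeaderPath <- function()
  system.file("extdata", "raxis_scan001.header", package = "reflQC")
brukerHeaderPath <- function()
  system.file("extdata", "bruker_frame001.header", package = "reflQC")
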