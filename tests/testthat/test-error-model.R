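test_that("the variance model equals its polynomial k-form", {
  nm0 <- noiseModel(0, 0, 0, gTrue = 0)
  expect_equal(varianceModel(0, nm0), 0)
  ## pure Poisson term
  expect_equal(varianceModel(400, nm0), 400)
  ## k-form and physical form agree for random parameter draws
  set.seed(9)
  for (i in 1:20) {
    nm <- noiseModel(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 10),
                     gTrue = runif(1, 0, 0.1))
    kk <- polynomialCoefficients(nm)
    I <- runif(1, 0, 1e4)
    expect_equal(varianceModel(I, nm),
                 kk["k0"] + kk["k1"] * I + kk["k2"] * I^2,
                 ignore_attr = TRUE)
  }
  ## negative net intensities do not reduce the Poisson term below zero
  nmBg <- noiseModel(1, 1, 2, gTrue = 0.05)
  expect_equal(varianceModel(-50, nmBg), 1 + 1 + 4 + (0.05 * 50)^2)
})

twoObs <- function(I, sigma) {
  mergeObservations(
    data.frame(h = 1, k = 2, l = 3, batch = seq_along(I), I = I,
               sigma = sigma, d = 5),
    laueClass("mmm"))
}

test_that("chi-square matches hand evaluation and is scale invariant", {
  ## group (90, 110), sigma 10: mean 100, per-group term
  ## N/(N-1) * sum(dev^2/sigma^2) = 2 * (100+100)/100 = 4, divided by
  ## the N = 2 observations
  expect_equal(chiSquare(twoObs(c(90, 110), c(10, 10))), 2)
  ## all members at the mean: zero
  expect_equal(chiSquare(twoObs(c(100, 100), c(10, 10))), 0)
  ## common rescaling of I and sigma leaves chi-square unchanged
  expect_equal(chiSquare(twoObs(c(900, 1100), c(100, 100))),
               chiSquare(twoObs(c(90, 110), c(10, 10))))
  ## undefined without a multiply-observed group
  single <- mergeObservations(
    data.frame(h = 1, k = 2, l = 3, batch = 1, I = 1, sigma = 1, d = 5),
    laueClass("mmm"))
  expect_error(chiSquare(single), "undefined")
})

test_that("chi-square is near 1 when delivered sigmas are correct", {
  ## g = 0 and K = 1: the delivered first-two-terms sigma is the truth
  cfg <- smallSimConfig(seed = 41L,
                        noise = noiseModel(gTrue = 0, KTrue = 1))
  sim <- simulateDataset(cfg)
  m <- mergeObservations(sim$observations, laueClass("mmm"))
  expect_lt(abs(chiSquare(m) - 1), 0.05)
})

test_that("error-model refinement recovers the generator parameters", {
  m <- bigMergedMmm()   # K_true = 1.2, g_true = 0.03, >= 5000 uniques
  em <- refineErrorModel(m)
  expect_true(em@converged)
  ## analytic mapping: K ~ K_true, g ~ g_true / sqrt(K_true)
  expect_lt(abs(errorK(em) - 1.2) / 1.2, 0.15)
  gExpected <- 0.03 / sqrt(1.2)
  expect_lt(abs(errorG(em) - gExpected) / gExpected, 0.15)
  ## corrected sigmas normalise the chi-square
  expect_lt(abs(chiSquareAfter(em) - 1), 0.1)
  expect_lt(abs(chiSquare(applyErrorModel(m, em)) - 1), 0.1)
  ## refining the corrected data is a fixed point: K -> 1, g -> 0
  em2 <- refineErrorModel(applyErrorModel(m, em))
  expect_lt(abs(errorK(em2) - 1), 0.1)
  expect_lt(errorG(em2), 0.01)
})

test_that("null data refine to K ~ 1, g ~ 0", {
  cfg <- smallSimConfig(seed = 42L, noise = noiseModel(gTrue = 0, KTrue = 1))
  m <- mergeObservations(simulateDataset(cfg)$observations, laueClass("mmm"))
  em <- refineErrorModel(m)
  expect_lt(abs(errorK(em) - 1), 0.1)
  expect_lt(errorG(em), 0.01)
})

test_that("degenerate input falls back to K = 1, g = 0 with a warning", {
  obs <- data.frame(h = rep(1:60, each = 2), k = 70, l = 3,
                    batch = 1, I = 100, sigma = 10, d = 3)
  m <- mergeObservations(obs, laueClass("mmm"))
  expect_warning(em <- refineErrorModel(m, minGroups = 10), "degenerate")
  expect_equal(errorK(em), 1)
  expect_equal(errorG(em), 0)
  expect_false(em@converged)
  ## too few groups is a hard error
  expect_error(refineErrorModel(twoObs(c(90, 110), c(10, 10))), "at least")
})

test_that("sigma-based rejection flags exactly the planted outlier", {
  ## nine I = 100 plus one I = 200, sigma 10: the 200 deviates by
  ## about 9-10 sigma from any consensus, everything else by < 1
  obs <- data.frame(h = 1, k = 2, l = 3, batch = 1:10,
                    I = c(rep(100, 9), 200), sigma = 10, d = 5)
  rej <- rejectOutliers(mergeObservations(obs, laueClass("mmm")))
  ot <- observationTable(rej$merged)
  expect_identical(rej$nRejected, 1L)
  expect_identical(which(ot$flagOutlier), 10L)
  ## all-equal group: nothing flagged
  obsEq <- data.frame(h = 1, k = 2, l = 3, batch = 1:5, I = 100,
                      sigma = 10, d = 5)
  expect_identical(
    rejectOutliers(mergeObservations(obsEq, laueClass("mmm")))$nRejected, 0L)
  ## pairs are never arbitrated
  expect_identical(rejectOutliers(twoObs(c(0, 1000), c(1, 1)))$nRejected, 0L)
  expect_error(rejectOutliers(mergeObservations(obsEq, laueClass("mmm")),
                              threshold = 0), "threshold")
})

test_that("rejection recovers planted ice contamination at high redundancy", {
  sim <- iceSim()   # default redundancy 20, three ice windows
  m <- mergeObservations(sim$observations, laueClass("mmm"))
  em <- refineErrorModel(m)
  rej <- rejectOutliers(applyErrorModel(m, em))
  ot <- observationTable(rej$merged)
  recall <- sum(ot$flagOutlier & ot$contaminated) / sum(ot$contaminated)
  expect_gte(recall, 0.9)
  ## false-positive rate stays small
  fpr <- sum(ot$flagOutlier & !ot$contaminated) / sum(!ot$contaminated)
  expect_lt(fpr, 0.01)
})

test_that("rejection recall does not degrade as redundancy grows", {
  recallAt <- function(redundancy, seed) {
    cfg <- smallSimConfig(seed = seed, targetRedundancy = redundancy,
                          iceWindows = defaultIceWindows())
    sim <- simulateDataset(cfg)
    m <- mergeObservations(sim$observations, laueClass("mmm"))
    rej <- rejectOutliers(applyErrorModel(m, refineErrorModel(m)))
    ot <- observationTable(rej$merged)
    sum(ot$flagOutlier & ot$contaminated) / sum(ot$contaminated)
  }
  lo <- mean(vapply(43:45, function(s) recallAt(6, s), numeric(1)))
  hi <- mean(vapply(43:45, function(s) recallAt(24, s), numeric(1)))
  expect_gte(hi, lo - 0.02)
})
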