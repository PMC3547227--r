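twoObsGroup <- function(I = c(90, 110), sigma = c(10, 10)) {
  data.frame(h = 1, k = 2, l = 3, batch = seq_along(I),
             I = I, sigma = sigma, d = 5)
}

test_that("group means are inverse-variance weighted", {
  ## equal sigmas: plain mean
  m <- mergeObservations(twoObsGroup(), laueClass("mmm"))
  expect_equal(groupTable(m)$Imean, 100)
  ## hand evaluation of sum(wI)/sum(w) with w = 1/sigma^2:
  ## (90/1 + 110/9) / (1 + 1/9) = 92
  m2 <- mergeObservations(twoObsGroup(sigma = c(1, 3)), laueClass("mmm"))
  expect_equal(groupTable(m2)$Imean, 92)
  expect_equal(groupTable(m2)$sigmaMean, 1 / sqrt(1 + 1 / 9))
  ## sigma of the mean never exceeds the best member's sigma, and the
  ## mean lies within the observed range
  g <- groupTable(m2)
  expect_lte(g$sigmaMean, 1)
  expect_true(g$Imean >= 90 && g$Imean <= 110)
})

test_that("grouping follows the asymmetric-unit mapping of the class", {
  obs <- data.frame(h = c(1, 2), k = c(2, 1), l = 3, batch = 1:2,
                    I = c(90, 110), sigma = 10, d = 5)
  expect_identical(nGroups(mergeObservations(obs, laueClass("4/mmm"))), 1L)
  expect_identical(nGroups(mergeObservations(obs, laueClass("mmm"))), 2L)
  ## flagged observations do not participate
  obs$flagIce <- c(FALSE, TRUE)
  m <- mergeObservations(obs, laueClass("4/mmm"))
  expect_identical(groupTable(m)$n, 1L)
  expect_true(is.na(observationTable(m)$groupId[2]))
  ## non-positive sigmas are rejected
  obs$flagIce <- FALSE
  obs$sigma <- c(10, 0)
  expect_error(mergeObservations(obs, laueClass("mmm")), "positive sigma")
})

test_that("R factors match hand-computed oracle values", {
  ref <- data.frame(h = 1, k = 2, l = 3, d = 5)
  s <- computeStats(mergeObservations(twoObsGroup(), laueClass("mmm")),
                    ref, nShells = 1)
  ## |90-100| + |110-100| over 200
  expect_equal(rMerge(s), 0.1)
  expect_equal(rMeas(s), sqrt(2) * 0.1)
  expect_equal(rPim(s), 0.1)   # sqrt(1/(n-1)) = 1 for pairs
  expect_equal(redundancy(s), 2)
  expect_equal(completeness(s), 1)

  ## three equal-sigma observations 90, 100, 110: mean 100,
  ## numerators 20 * {1, sqrt(3/2), sqrt(1/2)}, denominator 300
  obs3 <- data.frame(h = 1, k = 2, l = 3, batch = 1:3,
                     I = c(90, 100, 110), sigma = 10, d = 5)
  s3 <- computeStats(mergeObservations(obs3, laueClass("mmm")), ref, 1)
  expect_equal(rMerge(s3), 20 / 300)
  expect_equal(rMeas(s3), 20 * sqrt(3 / 2) / 300)
  expect_equal(rPim(s3), 20 * sqrt(1 / 2) / 300)

  ## identical observations in every group: all residuals zero
  sId <- computeStats(mergeObservations(twoObsGroup(I = c(100, 100)),
                                        laueClass("mmm")), ref, 1)
  expect_equal(rMerge(sId), 0)
  expect_equal(rMeas(sId), 0)
  expect_equal(rPim(sId), 0)
})

test_that("singleton-only data yields absent R factors and an error on an empty reference", {
  obs1 <- data.frame(h = 1, k = 2, l = 3, batch = 1, I = 100, sigma = 10,
                     d = 5)
  s <- computeStats(mergeObservations(obs1, laueClass("mmm")),
                    data.frame(h = 1, k = 2, l = 3, d = 5), 1)
  expect_true(is.na(rMerge(s)) && is.na(rMeas(s)) && is.na(rPim(s)))
  expect_equal(redundancy(s), 1)
  expect_error(computeStats(mergeObservations(obs1, laueClass("mmm")),
                            data.frame(h = integer(0), d = numeric(0)), 1),
               "empty")
})

test_that("r_pim <= r_merge <= r_meas on simulated data, per shell too", {
  for (seed in c(31L, 32L, 33L)) {
    sim <- simulateDataset(smallSimConfig(seed = seed))
    m <- mergeObservations(sim$observations, laueClass("mmm"))
    ref <- generateUnique(unitCell(40, 40, 30), laueClass("mmm"), 2.8, 20)
    s <- computeStats(m, ref, nShells = 8)
    expect_lte(rPim(s), rMerge(s))
    expect_lte(rMerge(s), rMeas(s))
    sh <- shellTable(s)
    expect_true(all(sh$rPim <= sh$rMerge & sh$rMerge <= sh$rMeas,
                    na.rm = TRUE))
    ## shells partition the groups and cover the resolution range
    expect_identical(sum(sh$nUnique), nGroups(m))
    expect_true(all(diff(sh$dMax) < 0))
  }
})

test_that("r_meas is redundancy-unbiased while r_merge is not", {
  ref <- generateUnique(unitCell(40, 40, 30), laueClass("mmm"), 2.8, 20)
  statsAt <- function(redundancy)
    computeStats(mergeObservations(
      simulateDataset(smallSimConfig(seed = 34L,
                                     targetRedundancy = redundancy))$observations,
      laueClass("mmm")), ref, 1)
  s4 <- statsAt(4)
  s16 <- statsAt(16)
  ## multiplicity-corrected residual is stable when redundancy quadruples
  expect_lt(abs(rMeas(s16) - rMeas(s4)) / rMeas(s4), 0.1)
  ## r_merge drifts up towards r_meas as groups grow
  expect_gt(rMerge(s16), rMerge(s4))
  expect_lt(rMeas(s4) - rMerge(s4), 0.2 * rMeas(s4))
})

test_that("completeness counts observed uniques against the reference", {
  ref <- generateUnique(unitCell(40, 40, 30), laueClass("mmm"), 2.8, 20)
  sim <- simulateDataset(smallSimConfig(seed = 35L))
  m <- mergeObservations(sim$observations, laueClass("mmm"))
  s <- computeStats(m, ref, 5)
  expect_equal(completeness(s), nGroups(m) / nrow(ref))
  expect_lte(completeness(s), 1)
})
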