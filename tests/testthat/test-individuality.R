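test_that("rank alignment sorts, ties, and ignores species labels", {
  # single run with constant populations (10, 5, 1)
  tr <- makeTrajectory(constantComp(20, c("30" = 10L, "7" = 5L, "900" = 1L)))
  ens <- new("TanaEnsemble", members = list(tr), horizon = 20L,
             masterSeed = 1, sharedJ = FALSE)
  ra <- rankAlign(ens, window = 1:20, nRanks = 3)
  expect_true(all(ra$pops[1, , 1] == 10))
  expect_true(all(ra$pops[1, , 2] == 5))
  expect_equal(ra$masses, c(10, 5, 1))

  # permuted species labels with identical sorted populations align
  trA <- makeTrajectory(constantComp(20, c("3" = 9L, "800" = 4L)))
  trB <- makeTrajectory(constantComp(20, c("555" = 9L, "2" = 4L)))
  eAB <- new("TanaEnsemble", members = list(trA, trB), horizon = 20L,
             masterSeed = 1, sharedJ = FALSE)
  raAB <- rankAlign(eAB, window = 1:20, nRanks = 2)
  expect_identical(raAB$pops[1, , ], raAB$pops[2, , ])

  # ties in time-averaged population break by ascending species id
  trT <- makeTrajectory(constantComp(20, c("9" = 5L, "4" = 5L)))
  eT <- new("TanaEnsemble", members = list(trT), horizon = 20L,
            masterSeed = 1, sharedJ = FALSE)
  raT <- rankAlign(eT, window = 1:20, nRanks = 2)
  # both series are constant 5; the tie rule is observable through the
  # deterministic repeatability of the alignment
  expect_identical(raT$pops, rankAlign(eT, window = 1:20, nRanks = 2)$pops)

  # more ranks than species is refused
  expect_error(rankAlign(eT, window = 1:20, nRanks = 5),
               class = "tana_refusal")
})

test_that("subset enumeration is best-first by summed mass", {
  expect_identical(enumerateSubsets(1, 3, c(10, 5, 1)),
                   matrix(1:3, 3, 1))
  e2 <- enumerateSubsets(2, 10, c(10, 5, 1))
  expect_identical(e2, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  # exhaustive case: every subset exactly once
  e3 <- enumerateSubsets(2, 100, c(4, 3, 2, 1))
  expect_equal(nrow(e3), choose(4, 2))
  expect_equal(nrow(unique(e3)), choose(4, 2))
  # brute-force oracle on a larger case: sort all subsets by
  # (-sum, lexicographic) and compare the truncated prefix
  masses <- c(9, 7.5, 7.5, 4, 2, 0.5)
  all3 <- t(utils::combn(6, 3))
  sums <- rowSums(matrix(masses[all3], nrow(all3)))
  key <- order(-sums, all3[, 1], all3[, 2], all3[, 3])
  got <- enumerateSubsets(3, 12, masses)
  expect_identical(got, all3[key[1:12], , drop = FALSE] + 0L)
  expect_error(enumerateSubsets(7, 5, masses), "exceeds")
  expect_error(enumerateSubsets(2, 5, c(1, 5, 3)), "non-increasing")
})

test_that("environment population is the complement of the subset", {
  expect_equal(environmentPop(475, c(60, 40)), 375)
  expect_equal(environmentPop(100, c(70, 30)), 0)
  expect_equal(environmentPop(100, numeric(0)), 100)
  expect_equal(environmentPop(c(10, 20), rbind(c(1, 2), c(3, 4))),
               c(7, 13))
  expect_error(environmentPop(50, c(60, 40)), "exceed")
})

test_that("individuality measures agree with their definitions", {
  # K = 1 organismal individuality is plain lag-1 ensemble MI
  spec <- varSpec(matrix(0.8), nEnsemble = 300, horizon = 10, seed = 21)
  arr <- simulateVAR(spec)
  ra <- list(pops = arr, totals = matrix(1000, 300, 10) + arr[, , 1],
             masses = 1, window = 1:9)
  a1 <- organismalIndividuality(ra, subset = 1)
  direct <- ensembleMeasure(arr, function(Xt, Xt1) gaussianMI(Xt, Xt1),
                            vars = 1, window = 1:9)
  expect_equal(a1$mean, direct$mean, tolerance = 1e-12)
  expect_equal(individualityScore(a1$mean, 1), a1$mean)

  # temporally independent ensembles carry no self-prediction
  spec0 <- varSpec(matrix(0, 2, 2), nEnsemble = 400, horizon = 8,
                   seed = 3)
  arr0 <- simulateVAR(spec0)
  ra0 <- list(pops = arr0, totals = matrix(500, 400, 8),
              masses = c(1, 1), window = 1:7)
  expect_lt(organismalIndividuality(ra0, subset = 1:2)$mean, 0.02)

  # nC is the environment-to-group transfer entropy, definitionally
  A <- matrix(c(0.5, 0, 0.3, 0.6), 2)   # env (var 2) drives var 1
  specE <- varSpec(A, nEnsemble = 500, horizon = 8, seed = 5)
  arrE <- simulateVAR(specE)
  totals <- 400 + arrE[, , 1] + arrE[, , 2]
  raE <- list(pops = arrE, totals = totals, masses = c(1, 1),
              window = 1:7)
  # here environmentPop(totals, S) reconstructs series 2 + constant
  nc <- environmentalIndividuality(raE, subset = 1)
  te <- transferEntropy(arrE[, , 2], arrE[, , 1], window = 1:7)
  expect_equal(nc$mean, te$mean, tolerance = 1e-10)
  # and it matches the analytic Gaussian transfer entropy
  truth <- analyticInfo(specE, "nc", subset = 1, env = 2)
  expect_lt(abs(nc$mean - truth), 0.02)

  # colonial individuality: conditioning on an irrelevant environment
  # changes nothing; near-deterministic dependence on E removes it
  specI <- varSpec(matrix(c(0.7, 0, 0, 0.5), 2), nEnsemble = 500,
                   horizon = 8, seed = 6)
  arrI <- simulateVAR(specI)
  raI <- list(pops = arrI, totals = 300 + arrI[, , 1] + arrI[, , 2],
              masses = c(1, 1), window = 1:7)
  aCol <- colonialIndividuality(raI, subset = 1)
  aStar <- organismalIndividuality(raI, subset = 1)
  expect_equal(aCol$mean, aStar$mean, tolerance = 0.1)
  truthA <- analyticInfo(specI, "a", subset = 1, env = 2)
  expect_equal(aCol$mean, truthA, tolerance = 0.1)
})

test_that("scores are invariant to species relabelling within runs", {
  comp <- list(c("5" = 30L, "100" = 12L, "7" = 4L))
  compP <- list(c("900" = 30L, "2" = 12L, "64" = 4L))
  mk <- function(cc, n = 30) {
    varying <- lapply(seq_len(n), function(g) {
      x <- cc[[1]]
      x + as.integer(round(3 * sin(g + seq_along(x))))
    })
    makeTrajectory(varying)
  }
  e1 <- new("TanaEnsemble",
            members = lapply(1:25, function(i) mk(comp)), horizon = 30L,
            masterSeed = 1, sharedJ = FALSE)
  e2 <- new("TanaEnsemble",
            members = lapply(1:25, function(i) mk(compP)), horizon = 30L,
            masterSeed = 1, sharedJ = FALSE)
  r1 <- rankAlign(e1, window = 1:30, nRanks = 1)
  r2 <- rankAlign(e2, window = 1:30, nRanks = 1)
  expect_identical(r1$pops, r2$pops)
})

test_that("the scale sweep recovers a planted block and surfaces refusals", {
  fx <- plantedBlockEnsemble(3, nRanks = 6, nEnsemble = 300,
                             horizon = 30, seed = 9)
  sw <- scaleSweep(fx, Krange = 1:5, subsetLimit = 1, stride = 2)
  expect_equal(sw$optimalScale, 3L)
  # scales beyond the safety ratio are reported, not dropped
  small <- fx
  small$pops <- fx$pops[1:50, , ]
  swS <- scaleSweep(small, Krange = c(1, 4), subsetLimit = 3, stride = 2)
  expect_equal(nrow(swS$table), 2L)
  expect_true(is.na(swS$table$meanScore[2]))
  expect_match(swS$table$refused[2], "below")
})
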