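test_that("interaction matrix respects the coupling probability", {
  p0 <- tanaParams(theta = 0, L = 6L, seed = 3)
  J0 <- interactionWeights(sampleInteractions(p0))
  expect_true(all(J0 == 0))

  p1 <- tanaParams(theta = 1, L = 6L, seed = 3)
  J1 <- interactionWeights(sampleInteractions(p1))
  off <- J1[row(J1) != col(J1)]
  expect_true(all(off != 0))
  expect_true(all(abs(off) <= 1))
  expect_true(all(diag(J1) == 0))

  # fraction of nonzero off-diagonal entries within a 99% binomial band
  p <- tanaParams(theta = 0.25, seed = 5)
  J <- interactionWeights(sampleInteractions(p))
  n <- 1024 * 1023
  frac <- sum(J != 0) / n
  half <- qnorm(0.995) * sqrt(0.25 * 0.75 / n)
  expect_gt(frac, 0.25 - half)
  expect_lt(frac, 0.25 + half)
})

test_that("neutral and pairwise interaction variants behave as declared", {
  p <- tanaParams(theta = 0.3, L = 6L, seed = 9)
  Jn <- interactionWeights(sampleInteractions(p, neutral = TRUE,
                                              neutralWeight = 0.1))
  expect_true(all(Jn %in% c(0, 0.1)))
  Jp <- interactionWeights(sampleInteractions(p, pairwise = TRUE))
  expect_identical(unname(Jp != 0), unname(t(Jp) != 0))
})

test_that("fitness follows the interaction/resource decomposition", {
  p <- tanaParams(mu = 1 / 143, k = 33, L = 10L)
  # no interactions, N = 143: H = -mu * N = -1
  st <- ecosystemState(c("7" = 143L))
  expect_equal(tanaFitness(7L, st, zeroInteraction(), p), -1)
  # single neighbour with J = 1 holding the whole population of 100
  J <- customInteraction(data.frame(i = 4L, j = 9L, w = 1))
  st2 <- ecosystemState(c("9" = 100L))
  expect_equal(tanaFitness(4L, st2, J, p), 33 - 100 / 143, tolerance = 1e-12)
  # mu = 0 and no interactions: both terms vanish
  p0 <- tanaParams(mu = 1e-300, k = 33)
  expect_equal(tanaFitness(4L, st2, zeroInteraction(), p0), 0,
               tolerance = 1e-12)
  # undefined on an empty ecosystem
  empty <- list(populations = integer(0), total = 0L, generation = 0L)
  expect_error(tanaFitness(0L, empty, zeroInteraction(), p), "undefined")
})

test_that("reproduction probability is the logistic link", {
  expect_equal(reproductionProb(0), 0.5)
  expect_equal(reproductionProb(-1), 1 / (1 + exp(1)))
  expect_equal(reproductionProb(1e4), 1)
  H <- seq(-5, 5, by = 0.25)
  pr <- reproductionProb(H)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(reproductionProb(Inf * c(1, NA)))
})

test_that("stubbed timestep honours the kill/birth/mutation contract", {
  p <- tanaParams(pMut = 0, seed = 1)
  J <- zeroInteraction()
  st <- ecosystemState(c("12" = 50L, "40" = 50L))
  # kill-draw fails, birth succeeds, no mutation: N + 1, parent species + 1
  out <- tanaStep(st, J, p, draws = list(kill = 0.99, birthPick = 0.01,
                                         birth = 0, bits = rep(1, 10),
                                         bits2 = rep(1, 10)))
  expect_equal(out$total, 101L)
  expect_equal(unname(out$populations["12"]), 51L)
  # kill succeeds, birth fails: N - 1
  out2 <- tanaStep(st, J, p, draws = list(kill = 0, killPick = 0.01,
                                          birthPick = 0.5, birth = 0.999))
  expect_equal(out2$total, 99L)
  expect_equal(unname(out2$populations["12"]), 49L)
})

test_that("forced full mutation yields the bitwise complement genome", {
  J <- zeroInteraction()
  st <- ecosystemState(c("12" = 100L))
  comp <- bitwXor(12L, 1023L)
  # budding: parent retained, one complement offspring
  pb <- tanaParams(pMut = 1, scheme = "budding")
  out <- tanaStep(st, J, pb, draws = list(kill = 0.99, birthPick = 0.5,
                                          birth = 0, bits = rep(0, 10)))
  expect_equal(unname(out$populations[as.character(comp)]), 1L)
  expect_equal(unname(out$populations["12"]), 100L)
  # replace: parent removed, two complement copies added
  pr <- tanaParams(pMut = 1, scheme = "replace")
  out2 <- tanaStep(st, J, pr, draws = list(kill = 0.99, birthPick = 0.5,
                                           birth = 0, bits = rep(0, 10),
                                           bits2 = rep(0, 10)))
  expect_equal(unname(out2$populations[as.character(comp)]), 2L)
  expect_equal(unname(out2$populations["12"]), 99L)
})

test_that("a generation executes round(N/pKill) timesteps", {
  p <- tanaParams(pMut = 0.01, n0 = 500L, pKill = 0.2, seed = 12)
  tr <- tanaRun(p, 1, recordTimesteps = TRUE)
  expect_length(attr(tr, "timestepTotals"), round(500 / 0.2))
})

test_that("without mutation no new species ever appears", {
  p <- tanaParams(pMut = 0, n0 = 200L, n0Species = 1L, seed = 8)
  tr <- tanaRun(p, 50)
  expect_length(unique(trajectoryRecords(tr)$speciesId), 1L)
})

test_that("a lethal environment drives extinction which is flagged", {
  # mu so large that reproduction probability is numerically zero:
  # with pKill = 1 every timestep removes one individual and extinction
  # must occur within n0 timesteps
  p <- tanaParams(pMut = 0.01, pKill = 1, mu = 1e6, n0 = 30L,
                  n0Species = 3L, seed = 4)
  tr <- tanaRun(p, 100, recordTimesteps = TRUE)
  expect_true(tr@terminatedEarly)
  expect_lte(length(attr(tr, "timestepTotals")), 30L)
})

test_that("population changes by at most one individual per timestep", {
  for (scheme in c("replace", "budding")) {
    p <- tanaParams(pMut = 0.03, scheme = scheme, seed = 21)
    tr <- tanaRun(p, 5, recordTimesteps = TRUE)
    ts <- attr(tr, "timestepTotals")
    expect_true(all(abs(diff(ts)) <= 1L))
    expect_true(all(trajectoryRecords(tr)$count >= 0L))
  }
})

test_that("trajectories are reproducible from (params, seed)", {
  p <- tanaParams(pMut = 0.02, seed = 99)
  tr1 <- tanaRun(p, 30)
  tr2 <- tanaRun(p, 30)
  expect_identical(trajectoryRecords(tr1), trajectoryRecords(tr2))
  expect_identical(trajectoryTotals(tr1), trajectoryTotals(tr2))
})

test_that("ensembles are seeded, independent, and horizon-complete", {
  p <- tanaParams(pMut = 0.02)
  e1 <- tanaEnsemble(p, nRuns = 3, nGenerations = 12, masterSeed = 5)
  e2 <- tanaEnsemble(p, nRuns = 3, nGenerations = 12, masterSeed = 5)
  expect_identical(lapply(e1@members, trajectoryRecords),
                   lapply(e2@members, trajectoryRecords))
  expect_equal(ensembleHorizon(e1), 12L)
  # different derived seeds give different histories
  expect_false(identical(trajectoryRecords(e1@members[[1]]),
                         trajectoryRecords(e1@members[[2]])))
  # members share one J under sharedJ, distinct ones otherwise
  eS <- tanaEnsemble(p, nRuns = 2, nGenerations = 5, masterSeed = 5,
                     sharedJ = TRUE)
  expect_equal(eS@members[[1]]@seedJ, eS@members[[2]]@seedJ)
  expect_false(e1@members[[1]]@seedJ == e1@members[[2]]@seedJ)
})

test_that("parameter validity is enforced", {
  expect_error(tanaParams(pMut = 1.5), "pMut")
  expect_error(tanaParams(mu = 0), "mu")
  expect_error(tanaParams(n0Species = 2000L, L = 10L, n0 = 4000L),
               "n0Species")
  expect_error(new("TanaInteraction",
                   weights = matrix(2, 2, 2) - diag(2, 2), neutral = FALSE,
                   pairwise = FALSE, seed = 0))
})
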