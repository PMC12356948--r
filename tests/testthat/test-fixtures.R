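test_that("VAR simulation is stationary, seeded, and Lyapunov-consistent", {
  A <- matrix(c(0.6, 0.2, 0, 0.5), 2)
  spec <- varSpec(A, nEnsemble = 1e4, horizon = 3, seed = 13)
  arr <- simulateVAR(spec)
  expect_identical(arr, simulateVAR(spec))

  # independent oracle for the stationary covariance: fixed-point
  # iteration of S <- A S A' + Q, no linear solve involved
  S <- diag(2)
  for (i in 1:500) S <- A %*% S %*% t(A) + diag(2)
  expect_equal(stationaryCov(spec), S, tolerance = 1e-10)

  # empirical lag-1 cross-covariance matches S0 %*% t(A)
  emp <- cov(arr[, 1, ], arr[, 2, ])   # cov(X(t), X(t+1))
  expect_equal(emp, S %*% t(A), tolerance = 0.1)

  # zero coefficients give temporally independent noise
  spec0 <- varSpec(matrix(0, 2, 2), nEnsemble = 4000, horizon = 2,
                   seed = 3)
  arr0 <- simulateVAR(spec0)
  expect_lt(gaussianMI(arr0[, 1, ], arr0[, 2, ]), 0.01)

  # non-stationary specifications are refused
  expect_error(varSpec(matrix(1.01), nEnsemble = 10, horizon = 5,
                       seed = 1), "spectral radius")
})

test_that("analytic information values match closed forms", {
  # univariate AR(1): lag-1 MI = -log(1 - a^2) / 2
  for (a in c(0.3, 0.7, 0.95)) {
    sp <- varSpec(matrix(a), nEnsemble = 10, horizon = 5, seed = 1)
    expect_equal(analyticInfo(sp, "mi", subset = 1), -0.5 * log(1 - a^2))
  }
  # diagonal coefficients and noise: no transfer between components
  spD <- varSpec(diag(c(0.5, 0.8)), nEnsemble = 10, horizon = 5, seed = 1)
  expect_equal(analyticInfo(spD, "te", source = 1, target = 2), 0,
               tolerance = 1e-12)
  # phi identity: phir - phiwms = min pairwise lagged MI
  A <- matrix(c(0.5, 0.25, 0.15, 0.6), 2)
  sp <- varSpec(A, nEnsemble = 10, horizon = 5, seed = 1)
  S0 <- stationaryCov(sp)
  C01 <- S0 %*% t(A)
  lagMI <- function(i, j) {
    C <- matrix(c(S0[i, i], C01[i, j], C01[i, j], S0[j, j]), 2)
    -0.5 * log(1 - C[1, 2]^2 / (C[1, 1] * C[2, 2]))
  }
  mins <- min(lagMI(1, 1), lagMI(1, 2), lagMI(2, 1), lagMI(2, 2))
  expect_equal(analyticInfo(sp, "phir", parts = c(1, 2)) -
                 analyticInfo(sp, "phiwms", parts = c(1, 2)),
               mins, tolerance = 1e-10)
})

test_that("every estimator converges to its analytic fixture value", {
  # 3-component process: coupled pair (1, 2) plus component 3 acting as
  # an environment influencing component 1
  A <- matrix(c(0.5, 0.2, 0.0,
                0.2, 0.5, 0.0,
                0.25, 0.0, 0.6), 3, byrow = TRUE)
  checks <- list(
    list(m = "mi", args = list(subset = 1:2)),
    list(m = "a", args = list(subset = 1:2, env = 3)),
    list(m = "nc", args = list(subset = 1:2, env = 3)),
    list(m = "te", args = list(source = 3, target = 1)),
    list(m = "phiwms", args = list(parts = 1:2)),
    list(m = "phir", args = list(parts = 1:2)))
  est <- function(arr, m, args, t = 1L) {
    sl <- function(i, tt) {
      x <- arr[, tt, i, drop = FALSE]; dim(x) <- c(dim(arr)[1], length(i)); x
    }
    switch(m,
      mi = gaussianMI(sl(args$subset, t), sl(args$subset, t + 1L)),
      a = gaussianCMI(sl(args$subset, t), sl(args$subset, t + 1L),
                      sl(args$env, t)),
      nc = gaussianCMI(sl(args$env, t), sl(args$subset, t + 1L),
                       sl(args$subset, t)),
      te = gaussianCMI(sl(args$source, t), sl(args$target, t + 1L),
                       sl(args$target, t)),
      phiwms = phiWMS(arr[, , args$parts[1]], arr[, , args$parts[2]],
                      window = t)$mean,
      phir = phiR(arr[, , args$parts[1]], arr[, , args$parts[2]],
                  window = t)$mean)
  }
  for (ck in checks) {
    truth <- do.call(analyticInfo,
                     c(list(varSpec(A, nEnsemble = 2, horizon = 2,
                                    seed = 0), ck$m), ck$args))
    errs <- vapply(c(100, 1000, 10000), function(n) {
      arr <- simulateVAR(varSpec(A, nEnsemble = n, horizon = 2,
                                 seed = n + 17))
      abs(est(arr, ck$m, ck$args) - truth)
    }, numeric(1))
    expect_lt(errs[3], max(errs[1], 0.02))
    expect_lt(errs[3], 0.03)
  }
})

test_that("planted-block fixtures plant what they claim", {
  # degenerate block: only rank 1 is self-predicting
  fx1 <- plantedBlockEnsemble(1, nRanks = 5, nEnsemble = 300,
                              horizon = 25, seed = 4)
  sw1 <- scaleSweep(fx1, Krange = 1:4, subsetLimit = 1, stride = 2)
  expect_equal(sw1$optimalScale, 1L)
  # masses are a valid (non-increasing) subset ordering key
  expect_true(all(diff(fx1$masses) <= 0))
  # vanishing coupling drives all scores to zero
  fx0 <- plantedBlockEnsemble(3, nRanks = 5, nEnsemble = 300,
                              horizon = 25, seed = 4,
                              selfCoupling = 0, coupling = 0)
  sw0 <- scaleSweep(fx0, Krange = 1:4, subsetLimit = 3, stride = 2)
  expect_lt(max(sw0$table$meanScore), 0.05)
  expect_equal(sw0$optimalScale, 1L)  # tie rule: smallest scale
})
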