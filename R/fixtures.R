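# ---- VAR(1) fixture processes with closed-form information ground truth ----
#
# The Gaussian estimators are validated against stationary first-order
# vector autoregressions, for which every measure the package estimates
# has an exact value computable from the stationary covariance and the
# lag-1 cross-covariance.

#' Construct a VAR(1) fixture specification
#'
#' @param A coefficient matrix (spectral radius < 1).
#' @param Sigma innovation covariance (symmetric positive definite);
#'   default identity.
#' @param nEnsemble number of independent realizations.
#' @param horizon time points per realization.
#' @param seed RNG seed.
#' @return A \linkS4class{VarSpec}.
#' @examples
#' varSpec(matrix(0.7), nEnsemble = 100, horizon = 50, seed = 1)
#' @export
varSpec <- function(A, Sigma = diag(nrow(A)), nEnsemble, horizon, seed) {
  A <- as.matrix(A)
  new("VarSpec", A = A, Sigma = as.matrix(Sigma),
      nEnsemble = as.integer(nEnsemble), horizon = as.integer(horizon),
      seed = as.numeric(seed))
}

#' @describeIn varSpec Stationary covariance of the process (solution of
#'   the discrete Lyapunov equation \code{S = A S A' + Sigma}).
#' @param spec a \code{VarSpec}.
#' @export
stationaryCov <- function(spec) {
  d <- nrow(spec@A)
  vecS <- solve(diag(d * d) - spec@A %x% spec@A, as.vector(spec@Sigma))
  matrix(vecS, d, d)
}

# run a block of code under a temporary RNG state seeded from `seed`
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Simulate a VAR(1) ensemble
#'
#' Independent stationary realizations of
#' \code{X(t+1) = A X(t) + eps, eps ~ N(0, Sigma)}, each initialized from
#' the exact stationary distribution so the whole array is stationary.
#' Fully reproducible from \code{(spec, seed)}.
#'
#' @param spec a \linkS4class{VarSpec}.
#' @return Numeric array \code{[run, time, dim]}.
#' @examples
#' arr <- simulateVAR(varSpec(matrix(0.7), nEnsemble = 50,
#'                            horizon = 20, seed = 4))
#' dim(arr)
#' @export
simulateVAR <- function(spec) {
  validObject(spec)
  d <- nrow(spec@A)
  S0 <- stationaryCov(spec)
  .withSeed(spec@seed, {
    n <- spec@nEnsemble
    X <- MASS::mvrnorm(n, mu = rep(0, d), Sigma = S0)
    if (n == 1L) X <- matrix(X, 1L, d)
    cholSig <- chol(spec@Sigma)
    arr <- array(0, c(n, spec@horizon, d))
    arr[, 1L, ] <- X
    At <- t(spec@A)
    for (t in seq_len(spec@horizon - 1L)) {
      eps <- matrix(rnorm(n * d), n, d) %*% cholSig
      X <- X %*% At + eps
      arr[, t + 1L, ] <- X
    }
    arr
  })
}

# exact Gaussian MI / CMI from a (noiseless) covariance matrix
.gmiCov <- function(C, ix, iy) {
  ld <- function(i) determinant(C[i, i, drop = FALSE],
                                logarithm = TRUE)$modulus
  0.5 * as.numeric(ld(ix) + ld(iy) - ld(c(ix, iy)))
}

.gcmiCov <- function(C, ix, iy, iz) {
  if (!length(iz)) return(.gmiCov(C, ix, iy))
  ld <- function(i) determinant(C[i, i, drop = FALSE],
                                logarithm = TRUE)$modulus
  0.5 * as.numeric(ld(c(ix, iz)) + ld(c(iy, iz)) - ld(iz) -
                     ld(c(ix, iy, iz)))
}

#' Closed-form information measures of a VAR(1) process
#'
#' Exact values from the stationary covariance \code{S0} and the lag-1
#' cross-covariance \code{S0 A'} via Gaussian determinant identities.
#' Variable indices refer to components of the process; time-\code{t}
#' and time-\code{t+1} copies are assembled into one joint covariance.
#'
#' Supported measures: \code{"mi"} (lag-1 MI between \code{subset} at
#' \code{t} and at \code{t+1}, i.e. organismal individuality
#' \eqn{A^*}), \code{"a"} (\eqn{I(S(t);S(t+1)|E(t))}), \code{"nc"}
#' (\eqn{I(E(t);S(t+1)|S(t))}), \code{"te"}
#' (\eqn{I(source(t); target(t+1)|target(t))}), \code{"phiwms"} and
#' \code{"phir"} (2-part integrated information of parts \code{i, j}).
#'
#' @param spec a \linkS4class{VarSpec}.
#' @param measure one of \code{"mi"}, \code{"a"}, \code{"nc"},
#'   \code{"te"}, \code{"phiwms"}, \code{"phir"}.
#' @param subset component indices of the group \code{S} (for
#'   \code{"mi"}, \code{"a"}, \code{"nc"}).
#' @param env component index of the environment \code{E} (for
#'   \code{"a"}, \code{"nc"}).
#' @param source,target component indices (for \code{"te"}).
#' @param parts length-2 component indices (for \code{"phiwms"},
#'   \code{"phir"}).
#' @return Exact value in nats.
#' @examples
#' sp <- varSpec(matrix(0.7), nEnsemble = 10, horizon = 10, seed = 1)
#' analyticInfo(sp, "mi", subset = 1)  # -0.5 * log(1 - 0.49)
#' @export
analyticInfo <- function(spec, measure = c("mi", "a", "nc", "te",
                                           "phiwms", "phir"),
                         subset = seq_len(nrow(spec@A)), env = NULL,
                         source = NULL, target = NULL, parts = NULL) {
  measure <- match.arg(measure)
  d <- nrow(spec@A)
  S0 <- stationaryCov(spec)
  C01 <- S0 %*% t(spec@A)           # cov(X(t), X(t+1))
  C <- rbind(cbind(S0, C01), cbind(t(C01), S0))
  at <- function(i) i                # index at time t
  at1 <- function(i) d + i           # index at time t+1
  switch(measure,
    mi = .gmiCov(C, at(subset), at1(subset)),
    a = {
      if (is.null(env)) stop("measure 'a' needs an env index")
      .gcmiCov(C, at(subset), at1(subset), at(env))
    },
    nc = {
      if (is.null(env)) stop("measure 'nc' needs an env index")
      .gcmiCov(C, at(env), at1(subset), at(subset))
    },
    te = {
      if (is.null(source) || is.null(target))
        stop("measure 'te' needs source and target indices")
      .gcmiCov(C, at(source), at1(target), at(target))
    },
    phiwms = ,
    phir = {
      if (is.null(parts) || length(parts) != 2L)
        stop("phi measures need exactly 2 parts")
      i <- parts[1]; j <- parts[2]
      wms <- .gmiCov(C, at(c(i, j)), at1(c(i, j))) -
        .gmiCov(C, at(i), at1(i)) - .gmiCov(C, at(j), at1(j))
      if (measure == "phiwms") wms
      else {
        pij <- c(.gmiCov(C, at(i), at1(i)), .gmiCov(C, at(i), at1(j)),
                 .gmiCov(C, at(j), at1(i)), .gmiCov(C, at(j), at1(j)))
        wms + min(pij)
      }
    })
}

#' Planted-block fixture for scale recovery
#'
#' Generates rank-aligned-like ensemble arrays in which ranks
#' \code{1..K0} follow a mutually coupled stationary VAR(1) block with
#' strong joint self-prediction while the remaining ranks are temporally
#' independent noise.  Per-rank marginal variances and means decrease
#' with rank, emulating the ordering of rank-aligned populations; means
#' are shifted positive to emulate counts.  \code{\link{scaleSweep}} on
#' this fixture should recover the optimal scale \code{K0}.
#'
#' @param K0 planted block size.
#' @param nRanks total number of ranks (>= K0).
#' @param nEnsemble number of realizations.
#' @param horizon time points.
#' @param seed RNG seed.
#' @param selfCoupling VAR self-coefficient of block members.
#' @param coupling VAR cross-coefficient between block members (scaled by
#'   block size to keep the process stationary).
#' @return List with \code{pops} (\code{[run, time, rank]} array),
#'   \code{masses}, \code{window} and \code{spec} (the underlying
#'   \linkS4class{VarSpec}); drop-in input for \code{\link{scaleSweep}}.
#' @examples
#' fx <- plantedBlockEnsemble(3, nRanks = 6, nEnsemble = 200,
#'                            horizon = 30, seed = 2)
#' scaleSweep(fx, Krange = 1:5, subsetLimit = 1)$optimalScale  # 3
#' @export
plantedBlockEnsemble <- function(K0, nRanks = 8L, nEnsemble = 400L,
                                 horizon = 40L, seed = 1,
                                 selfCoupling = 0.2, coupling = 0.65) {
  stopifnot(K0 >= 1L, K0 <= nRanks)
  A <- matrix(0, nRanks, nRanks)
  if (K0 == 1L) {
    A[1, 1] <- 0.8
  } else {
    b <- coupling / (K0 - 1)
    A[seq_len(K0), seq_len(K0)] <- b
    diag(A)[seq_len(K0)] <- selfCoupling
  }
  # innovation variances decrease with rank so marginal variances (and
  # hence the rank-mass ordering) do too
  v <- 1.6 ^ (-(seq_len(nRanks) - 1L))
  spec <- varSpec(A, Sigma = diag(v), nEnsemble = nEnsemble,
                  horizon = horizon, seed = seed)
  arr <- simulateVAR(spec)
  sds <- sqrt(diag(stationaryCov(spec)))
  mu <- 100 * 1.4 ^ (-(seq_len(nRanks) - 1L)) + 6 * sds
  for (r in seq_len(nRanks)) arr[, , r] <- arr[, , r] + mu[r]
  list(pops = arr, masses = mu, window = seq_len(horizon - 1L),
       spec = spec)
}
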