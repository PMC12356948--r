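#' @import methods
#' @importFrom data.table as.data.table .SD :=
#' @importFrom stats cov rnorm runif sd setNames
#' @importFrom utils head tail write.csv
#' @useDynLib TangledNature, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# data.table non-standard-evaluation column names
utils::globalVariables(c("generation", "count"))

#' Parameters of the Tangled Nature model
#'
#' Container for every parameter of a Tangled Nature simulation: genome
#' length, interaction-network connectivity, death/mutation probabilities,
#' interaction strength, resource constraint, initial condition and the RNG
#' seed.  The model evolves a population of asexually reproducing agents,
#' each belonging to a species identified by a binary pangenome of
#' \code{L} bits; reproduction probability follows a logistic function of a
#' fitness that sums random inter-species interactions and a density
#' penalty.
#'
#' @slot L integer, genome length in bits (species space has \code{2^L}
#'   members).
#' @slot theta numeric in \[0,1\], probability that a directed interaction
#'   between two species is permitted.
#' @slot pKill numeric in \[0,1\], per-timestep death probability.
#' @slot pMut numeric in \[0,1\], per-bit mutation probability of an
#'   offspring genome.
#' @slot k numeric > 0, scaling of the interaction strength.
#' @slot mu numeric > 0, inverse carrying capacity (per-individual fitness
#'   penalty per unit population).
#' @slot n0 integer >= 1, initial total population.
#' @slot n0Species integer >= 1, number of initially occupied species.
#' @slot scheme character, reproduction scheme: \code{"replace"} (the
#'   original model: a reproducing parent is replaced by two
#'   independently mutated copies, net +1 individual) or
#'   \code{"budding"} (parent retained, one mutated offspring added).
#' @slot seed numeric, master RNG seed of the run.
#' @export
setClass("TanaParams",
  slots = c(L = "integer", theta = "numeric", pKill = "numeric",
            pMut = "numeric", k = "numeric", mu = "numeric",
            n0 = "integer", n0Species = "integer", scheme = "character",
            seed = "numeric"))

setValidity("TanaParams", function(object) {
  msgs <- character()
  p01 <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      sprintf("%s must be a single value in [0, 1]", nm)
    else character()
  }
  msgs <- c(msgs, p01(object@theta, "theta"), p01(object@pKill, "pKill"),
            p01(object@pMut, "pMut"))
  if (object@L < 1L) msgs <- c(msgs, "L must be >= 1")
  if (!(object@mu > 0)) msgs <- c(msgs, "mu must be > 0")
  if (!(object@k > 0)) msgs <- c(msgs, "k must be > 0")
  if (object@n0 < 1L) msgs <- c(msgs, "n0 must be >= 1")
  if (object@n0Species < 1L || object@n0Species > 2^object@L)
    msgs <- c(msgs, "n0Species must be in [1, 2^L]")
  if (object@n0Species > object@n0)
    msgs <- c(msgs, "n0Species cannot exceed n0")
  if (!object@scheme %in% c("replace", "budding"))
    msgs <- c(msgs, "scheme must be 'replace' or 'budding'")
  if (length(msgs)) msgs else TRUE
})

#' Interaction matrix of the Tangled Nature model
#'
#' Dense \code{2^L x 2^L} matrix of directed interaction weights
#' \code{J[i, j]}: the per-capita influence of species \code{j} on the
#' fitness of species \code{i}.  Permitted entries are Uniform(-1, 1)
#' (or one shared constant in the neutral control); non-permitted entries
#' and the diagonal are exactly zero.
#'
#' @slot weights numeric matrix of interaction weights.
#' @slot neutral logical, whether all permitted weights are one constant.
#' @slot pairwise logical, whether the coupling mask was drawn per
#'   unordered pair (both directions together) rather than per directed
#'   entry.
#' @slot seed numeric, seed the matrix was drawn from.
#' @export
setClass("TanaInteraction",
  slots = c(weights = "matrix", neutral = "logical", pairwise = "logical",
            seed = "numeric"))

setValidity("TanaInteraction", function(object) {
  W <- object@weights
  msgs <- character()
  if (nrow(W) != ncol(W)) msgs <- c(msgs, "weights must be square")
  if (any(diag(W) != 0)) msgs <- c(msgs, "diagonal entries must be 0")
  if (any(abs(W) > 1)) msgs <- c(msgs, "|J[i,j]| must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Single-run trajectory of the Tangled Nature model
#'
#' Sparse per-generation record of one simulation: for every recorded
#' generation, the identities and counts of all occupied species.  A
#' generation is \code{round(N(t)/pKill)} elementary birth/death
#' timesteps, i.e. the expected time to turn over the whole population.
#'
#' @slot params the \linkS4class{TanaParams} of the run.
#' @slot records data.frame with columns \code{generation},
#'   \code{speciesId} (in \code{[0, 2^L)}) and \code{count}.
#' @slot totals integer vector, total population \code{N(t)} per recorded
#'   generation.
#' @slot terminatedEarly logical, whether the run went extinct before the
#'   requested horizon.
#' @slot seedRun,seedJ numeric, derived seeds of the dynamics stream and
#'   the interaction-matrix stream.
#' @slot neutral logical, neutral-control flag of the interaction matrix.
#' @export
setClass("TanaTrajectory",
  slots = c(params = "TanaParams", records = "data.frame",
            totals = "integer", terminatedEarly = "logical",
            seedRun = "numeric", seedJ = "numeric", neutral = "logical"))

setValidity("TanaTrajectory", function(object) {
  msgs <- character()
  g <- object@records$generation
  if (length(object@totals) == 0L && !object@terminatedEarly)
    msgs <- c(msgs, "records must be non-empty for a completed run")
  if (length(g) && !all(diff(unique(g)) == 1L))
    msgs <- c(msgs, "generations must increase strictly by 1")
  if (length(g) && any(object@records$count < 0L))
    msgs <- c(msgs, "species counts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Ensemble of Tangled Nature trajectories
#'
#' Aligned collection of independent runs sharing every parameter except
#' the seed (and, by default, the realized interaction matrix).  The
#' cross-run distribution at a fixed generation is the sampling
#' distribution every ensemble information estimator works on.
#'
#' @slot members list of \linkS4class{TanaTrajectory}.
#' @slot horizon integer, common number of generations (<= the shortest
#'   member).
#' @slot masterSeed numeric, seed all member seeds were derived from.
#' @slot sharedJ logical, whether one interaction matrix was shared across
#'   members.
#' @export
setClass("TanaEnsemble",
  slots = c(members = "list", horizon = "integer", masterSeed = "numeric",
            sharedJ = "logical"))

setValidity("TanaEnsemble", function(object) {
  msgs <- character()
  if (!length(object@members)) msgs <- c(msgs, "ensemble must have members")
  ok <- vapply(object@members, is, logical(1), class2 = "TanaTrajectory")
  if (!all(ok)) msgs <- c(msgs, "all members must be TanaTrajectory")
  if (all(ok) && length(object@members)) {
    lens <- vapply(object@members, function(m) length(m@totals), integer(1))
    if (object@horizon > min(lens))
      msgs <- c(msgs, "horizon exceeds the shortest member")
    key <- function(m) {
      p <- m@params
      paste(p@L, p@theta, p@pKill, p@pMut, p@k, p@mu, p@n0, p@n0Species,
            p@scheme)
    }
    if (length(unique(vapply(object@members, key, character(1)))) != 1L)
      msgs <- c(msgs, "members must share all parameters except seeds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Segmentation of a trajectory into q-ESS and reorganization epochs
#'
#' Labels every analyzed generation of a run as belonging to a
#' quasi-evolutionary-stable state (a metastable epoch during which the
#' core set of abundant species is conserved) or to a reorganization
#' burst between such epochs.
#'
#' @slot segments data.frame with columns \code{start}, \code{end}
#'   (generation indices, inclusive) and \code{label} (\code{"qess"} or
#'   \code{"reorg"}); segments tile the analyzed window.
#' @slot detector list of detector parameters (occupancy threshold rule,
#'   Jaccard similarity threshold, minimum q-ESS length).
#' @export
setClass("QessSegmentation",
  slots = c(segments = "data.frame", detector = "list"))

setValidity("QessSegmentation", function(object) {
  s <- object@segments
  msgs <- character()
  if (!all(c("start", "end", "label") %in% names(s)))
    return("segments needs columns start, end, label")
  if (nrow(s)) {
    if (any(s$end < s$start)) msgs <- c(msgs, "segment end before start")
    if (nrow(s) > 1L && any(s$start[-1L] != s$end[-nrow(s)] + 1L))
      msgs <- c(msgs, "segments must tile the window without gaps/overlap")
    if (!all(s$label %in% c("qess", "reorg")))
      msgs <- c(msgs, "labels must be 'qess' or 'reorg'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Specification of a stationary VAR(1) fixture process
#'
#' Defines an ensemble of independent stationary first-order vector
#' autoregressions \code{X(t+1) = A X(t) + eps}, used as an analytically
#' tractable stand-in for simulation ensembles when validating the
#' Gaussian information estimators.
#'
#' @slot A numeric coefficient matrix with spectral radius < 1.
#' @slot Sigma numeric symmetric positive-definite innovation covariance.
#' @slot nEnsemble integer, number of independent realizations.
#' @slot horizon integer, number of time points per realization.
#' @slot seed numeric RNG seed.
#' @export
setClass("VarSpec",
  slots = c(A = "matrix", Sigma = "matrix", nEnsemble = "integer",
            horizon = "integer", seed = "numeric"))

setValidity("VarSpec", function(object) {
  msgs <- character()
  d <- nrow(object@A)
  if (ncol(object@A) != d) msgs <- c(msgs, "A must be square")
  if (!isTRUE(all.equal(object@Sigma, t(object@Sigma))))
    msgs <- c(msgs, "Sigma must be symmetric")
  if (nrow(object@Sigma) != d || ncol(object@Sigma) != d)
    msgs <- c(msgs, "Sigma must match the dimension of A")
  else if (min(eigen(object@Sigma, symmetric = TRUE,
                     only.values = TRUE)$values) <= 0)
    msgs <- c(msgs, "Sigma must be positive definite")
  if (ncol(object@A) == d && max(Mod(eigen(object@A,
                                           only.values = TRUE)$values)) >= 1)
    msgs <- c(msgs, "A must have spectral radius < 1 (stationarity)")
  if (object@nEnsemble < 1L) msgs <- c(msgs, "nEnsemble must be >= 1")
  if (object@horizon < 2L) msgs <- c(msgs, "horizon must be >= 2")
  if (length(msgs)) msgs else TRUE
})
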