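#' Construct Tangled Nature model parameters
#'
#' Defaults are the standard parameterization of the model: genome length
#' \code{L = 10} (1024 possible species), connectivity \code{theta = 0.25},
#' death probability \code{pKill = 0.2}, interaction scaling \code{k = 33}
#' and inverse carrying capacity \code{mu = 1/143}.  The mutation rate
#' \code{pMut} is the swept control parameter and has no privileged
#' default beyond a low-rate regime value.
#'
#' @param L genome length in bits.
#' @param theta coupling probability in \[0,1\].
#' @param pKill per-timestep death probability.
#' @param pMut per-bit mutation probability.
#' @param k interaction scaling.
#' @param mu inverse carrying capacity.
#' @param n0 initial total population.
#' @param n0Species number of initially occupied species.
#' @param scheme reproduction scheme: \code{"replace"} (original model:
#'   the parent is replaced by two independently mutated copies) or
#'   \code{"budding"} (parent retained, one mutated offspring).  The
#'   replacement scheme subjects every lineage to mutation load at each
#'   reproduction and sets the error threshold near
#'   \code{pMut = 0.05} for \code{L = 10}; budding mutates offspring
#'   only, pushing the threshold far higher.
#' @param seed master RNG seed.
#' @return A \linkS4class{TanaParams} object.
#' @examples
#' tanaParams(pMut = 0.01, seed = 1)
#' @export
tanaParams <- function(pMut = 0.01, L = 10L, theta = 0.25, pKill = 0.2,
                       k = 33, mu = 1 / 143, n0 = 500L, n0Species = 10L,
                       scheme = c("replace", "budding"), seed = 1) {
  new("TanaParams", L = as.integer(L), theta = theta, pKill = pKill,
      pMut = pMut, k = k, mu = mu, n0 = as.integer(n0),
      n0Species = as.integer(n0Species), scheme = match.arg(scheme),
      seed = as.numeric(seed))
}

#' @describeIn tanaParams Number of possible species \code{2^L}.
#' @param object,params a \code{TanaParams} object.
#' @export
nSpeciesTotal <- function(params) 2L^params@L

setMethod("show", "TanaParams", function(object) {
  cat("TanaParams: L =", object@L, "(", 2^object@L, "species ), theta =",
      object@theta, "\n  pKill =", object@pKill, ", pMut =", object@pMut,
      ", k =", object@k, ", mu =", signif(object@mu, 5), "\n  n0 =",
      object@n0, "over", object@n0Species, "species, seed =",
      object@seed, "\n")
})

# derive a 64-bit stream seed (returned as an exact double) from a master
# seed and a stream index; used for every independent randomness source
deriveSeed <- function(masterSeed, stream) {
  .cpp_derive_seed(as.numeric(masterSeed), as.numeric(stream))
}

#' Sample a random interaction matrix
#'
#' Every directed off-diagonal entry is permitted independently with
#' probability \code{theta}; permitted entries are drawn Uniform(-1, 1).
#' With \code{pairwise = TRUE} a single coin per unordered pair decides
#' whether both directed entries are permitted (their values stay
#' independent).  With \code{neutral = TRUE} every permitted entry is
#' replaced by the single constant \code{neutralWeight}, the neutral
#' control in which no interaction structure can be selected for.
#'
#' @param params a \linkS4class{TanaParams} object.
#' @param seed RNG seed for the matrix draw; defaults to a stream derived
#'   from \code{params@seed}.
#' @param pairwise logical, couple directed entries per unordered pair.
#' @param neutral logical, neutral (constant-weight) control.
#' @param neutralWeight the shared weight used when \code{neutral}.
#' @return A \linkS4class{TanaInteraction} object.
#' @examples
#' J <- sampleInteractions(tanaParams(seed = 7, L = 5L))
#' mean(interactionWeights(J) != 0)  # close to theta
#' @export
sampleInteractions <- function(params, seed = deriveSeed(params@seed, 2L),
                               pairwise = FALSE, neutral = FALSE,
                               neutralWeight = 0.1) {
  validObject(params)
  W <- .cpp_sample_interactions(nSpeciesTotal(params), params@theta,
                                as.numeric(seed), pairwise, neutral,
                                neutralWeight)
  new("TanaInteraction", weights = W, neutral = neutral,
      pairwise = pairwise, seed = as.numeric(seed))
}

#' @describeIn sampleInteractions Extract the weight matrix.
#' @param J a \code{TanaInteraction} object.
#' @export
interactionWeights <- function(J) J@weights

setMethod("show", "TanaInteraction", function(object) {
  M <- nrow(object@weights)
  nz <- sum(object@weights != 0)
  cat("TanaInteraction:", M, "x", M,
      sprintf("(%.1f%% nonzero)", 100 * nz / (M * (M - 1))),
      if (object@neutral) "[neutral]" else "", "\n")
})

#' Ecosystem state at one generation
#'
#' A sparse snapshot of the ecosystem: counts of every occupied species.
#'
#' @param populations named integer vector of counts; names are species
#'   ids in \code{[0, 2^L)}.
#' @param generation integer generation index.
#' @return A list of class \code{tana_state} with elements
#'   \code{populations}, \code{total} and \code{generation}.
#' @examples
#' ecosystemState(c("3" = 10L, "5" = 2L))
#' @export
ecosystemState <- function(populations, generation = 0L) {
  populations <- populations[populations > 0L]
  stopifnot(all(populations >= 0), !is.null(names(populations)))
  structure(list(populations = populations,
                 total = sum(populations),
                 generation = as.integer(generation)),
            class = "tana_state")
}

#' Fitness of a species in a given ecosystem state
#'
#' The fitness of species \code{i} is
#' \deqn{H_i = (k / N) \sum_j J_{ij} n_j - \mu N,}
#' the population-weighted sum of incoming interaction weights, scaled by
#' \code{k/N}, minus the resource-constraint penalty \code{mu * N}.
#'
#' @param i species id (0-based genome integer).
#' @param state a \code{tana_state} (see \code{\link{ecosystemState}}).
#' @param J a \linkS4class{TanaInteraction}.
#' @param params a \linkS4class{TanaParams}.
#' @return The fitness value (a real number).
#' @examples
#' p <- tanaParams(seed = 1)
#' st <- ecosystemState(c("0" = 143L))
#' J0 <- new("TanaInteraction", weights = matrix(0, 1024, 1024),
#'           neutral = FALSE, pairwise = FALSE, seed = 0)
#' tanaFitness(0L, st, J0, p)  # -mu * N = -1
#' @export
tanaFitness <- function(i, state, J, params) {
  if (state$total <= 0) stop("fitness is undefined for an empty ecosystem")
  ids <- as.integer(names(state$populations))
  w <- J@weights[i + 1L, ids + 1L]
  (params@k / state$total) * sum(w * state$populations) -
    params@mu * state$total
}

#' Reproduction probability from fitness
#'
#' The logistic link between fitness and the per-draw offspring
#' probability, \code{1 / (1 + exp(-H))}.  Strictly increasing in
#' \code{H} and bounded in (0, 1), so even maladapted species retain a
#' small chance to reproduce and mutate toward fitter genomes.
#'
#' @param H fitness value(s).
#' @return Probability in (0, 1), vectorized over \code{H}.
#' @examples
#' reproductionProb(0)   # 0.5
#' reproductionProb(-1)  # 1/(1 + e)
#' @export
reproductionProb <- function(H) {
  stopifnot(all(is.finite(H)))
  1 / (1 + exp(-H))
}

#' One elementary timestep of the model (reference implementation)
#'
#' A timestep is an annihilation draw followed by a reproduction draw:
#' (a) with probability \code{pKill}, one individual chosen uniformly at
#' random dies; (b) if any individuals remain, one individual chosen
#' uniformly at random produces an offspring with probability
#' \code{reproductionProb(H)} of its species, each offspring genome bit
#' flipping independently with probability \code{pMut}.  This pure R
#' version exists as a testable contract (all random draws can be
#' injected); production runs use the compiled loop in
#' \code{\link{tanaRun}}.
#'
#' @param state a \code{tana_state}.
#' @param J a \linkS4class{TanaInteraction}.
#' @param params a \linkS4class{TanaParams}.
#' @param draws optional list of unit-interval draws replacing the RNG:
#'   \code{kill} (annihilation coin), \code{killPick}, \code{birthPick}
#'   (individual selectors), \code{birth} (offspring coin), \code{bits}
#'   (length-\code{L} vector of per-bit mutation coins for the first
#'   copy) and, under the \code{"replace"} scheme, \code{bits2} (second
#'   copy).
#' @return The new \code{tana_state}; if the population reached zero, the
#'   state carries attribute \code{extinct = TRUE} and a condition of
#'   class \code{tana_extinction} is signaled as a warning.
#' @examples
#' p <- tanaParams(seed = 1)
#' J <- sampleInteractions(p)
#' st <- ecosystemState(c("12" = 50L, "40" = 50L))
#' tanaStep(st, J, p, draws = list(kill = 1, birthPick = 0,
#'                                 birth = 0, bits = rep(1, 10)))
#' @export
tanaStep <- function(state, J, params, draws = NULL) {
  stopifnot(state$total > 0)
  d <- function(name, n = 1L) {
    if (!is.null(draws) && !is.null(draws[[name]])) draws[[name]]
    else runif(n)
  }
  pops <- state$populations
  total <- state$total
  pickIndividual <- function(u) {
    r <- floor(u * total) + 1L
    ids <- as.integer(names(pops))
    ids[findInterval(r - 1L, cumsum(pops))  + 1L]
  }
  # annihilation
  if (d("kill") < params@pKill) {
    victim <- pickIndividual(d("killPick"))
    key <- as.character(victim)
    pops[key] <- pops[key] - 1L
    total <- total - 1L
    pops <- pops[pops > 0L]
  }
  if (total == 0L) {
    warning(warningCondition("ecosystem went extinct",
                             class = "tana_extinction"))
    return(structure(ecosystemState(setNames(integer(0), character(0))[0],
                                    state$generation),
                     extinct = TRUE))
  }
  # reproduction
  parent <- pickIndividual(d("birthPick"))
  st <- ecosystemState(pops, state$generation)
  H <- tanaFitness(parent, st, J, params)
  if (d("birth") < reproductionProb(H)) {
    mutate <- function(u) {
      flips <- u < params@pMut
      bitwXor(parent, sum(2L^(seq_len(params@L) - 1L)[flips]))
    }
    addOne <- function(sp) {
      key <- as.character(sp)
      pops[key] <<- if (key %in% names(pops)) pops[key] + 1L else 1L
    }
    if (params@scheme == "replace") {
      pops[as.character(parent)] <- pops[as.character(parent)] - 1L
      addOne(mutate(d("bits", params@L)))
      addOne(mutate(d("bits2", params@L)))
      pops <- pops[pops > 0L]
    } else {
      addOne(mutate(d("bits", params@L)))
    }
    total <- total + 1L
  }
  ecosystemState(pops, state$generation)
}

#' Run one Tangled Nature trajectory
#'
#' Initializes \code{n0} individuals spread uniformly over
#' \code{n0Species} randomly chosen species, then iterates generations.
#' Each generation consists of \code{max(1, round(N(t)/pKill))} elementary
#' timesteps (with \code{N(t)} the population at the generation's start),
#' i.e. the expected number of draws needed to kill every currently
#' living individual; the state is recorded after each generation.
#' Extinction terminates the run early and is flagged, never silently
#' dropped.
#'
#' @param params a \linkS4class{TanaParams}.
#' @param nGenerations number of generations to simulate.
#' @param J optional \linkS4class{TanaInteraction} to use; by default a
#'   matrix is drawn from a seed stream derived from \code{params@seed}.
#' @param neutral,pairwise,neutralWeight interaction-matrix options, see
#'   \code{\link{sampleInteractions}}; ignored when \code{J} is given.
#' @param recordTimesteps logical; additionally record the total
#'   population after every elementary timestep (for contract checking on
#'   short runs only).
#' @return A \linkS4class{TanaTrajectory}.
#' @examples
#' tr <- tanaRun(tanaParams(pMut = 0.01, seed = 42), nGenerations = 20)
#' tail(trajectoryTotals(tr))
#' @export
tanaRun <- function(params, nGenerations, J = NULL, neutral = FALSE,
                    pairwise = FALSE, neutralWeight = 0.1,
                    recordTimesteps = FALSE) {
  validObject(params)
  stopifnot(nGenerations >= 1)
  seedRun <- deriveSeed(params@seed, 1L)
  seedJ <- if (is.null(J)) deriveSeed(params@seed, 2L) else J@seed
  if (!is.null(J)) {
    neutral <- J@neutral
    pairwise <- J@pairwise
  }
  res <- .cpp_tana_run(params@L, params@theta, params@pKill, params@pMut,
                       params@k, params@mu, params@n0, params@n0Species,
                       as.integer(nGenerations), seedRun, seedJ,
                       if (is.null(J)) NULL else J@weights,
                       pairwise, neutral, neutralWeight,
                       params@scheme == "replace", recordTimesteps)
  records <- data.frame(
    generation = rep.int(seq_len(res$n_generations), res$gen_sizes),
    speciesId = res$species,
    count = res$counts)
  tr <- new("TanaTrajectory", params = params, records = records,
            totals = res$totals, terminatedEarly = res$terminated_early,
            seedRun = seedRun, seedJ = seedJ, neutral = neutral)
  if (recordTimesteps) attr(tr, "timestepTotals") <- res$timestep_totals
  tr
}

#' @describeIn tanaRun Total population per recorded generation.
#' @param traj a \code{TanaTrajectory}.
#' @export
trajectoryTotals <- function(traj) traj@totals

#' @describeIn tanaRun Sparse per-generation records
#'   (generation, speciesId, count).
#' @export
trajectoryRecords <- function(traj) traj@records

#' @describeIn tanaRun Number of recorded generations.
#' @export
nGenerations <- function(traj) length(traj@totals)

setMethod("show", "TanaTrajectory", function(object) {
  G <- length(object@totals)
  cat("TanaTrajectory:", G, "generations, pMut =", object@params@pMut,
      "\n  final N =", if (G) object@totals[G] else 0L,
      ", occupied species =",
      if (G) sum(object@records$generation == G) else 0L,
      if (object@terminatedEarly) "(terminated early: extinction)" else "",
      "\n")
})

#' Simulate an ensemble of independent runs
#'
#' Runs \code{nRuns} independent trajectories sharing every parameter but
#' the seed.  Per-run seeds are derived deterministically from
#' \code{masterSeed} with a counter-based scheme, so the whole ensemble
#' is reproducible from one integer.  By default each run draws its own
#' interaction matrix and initial condition; \code{sharedJ = TRUE}
#' shares a single matrix across members.  Extinct runs are retained but
#' flagged; downstream ensemble statistics exclude them by default.
#'
#' @param params a \linkS4class{TanaParams} (its \code{seed} slot is
#'   ignored in favour of \code{masterSeed}).
#' @param nRuns number of independent runs.
#' @param nGenerations horizon per run.
#' @param masterSeed seed from which every per-run seed is derived.
#' @param sharedJ logical, share one interaction matrix across members.
#' @param ... further arguments passed to \code{\link{tanaRun}}
#'   (e.g. \code{neutral}).
#' @return A \linkS4class{TanaEnsemble}.
#' @examples
#' ens <- tanaEnsemble(tanaParams(pMut = 0.02), nRuns = 3,
#'                     nGenerations = 15, masterSeed = 99)
#' ensembleHorizon(ens)
#' @export
tanaEnsemble <- function(params, nRuns, nGenerations,
                         masterSeed = params@seed, sharedJ = FALSE, ...) {
  stopifnot(nRuns >= 1)
  J <- if (sharedJ) {
    p0 <- params
    p0@seed <- deriveSeed(masterSeed, 0L)
    sampleInteractions(p0, seed = p0@seed, ...)
  } else NULL
  members <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    p <- params
    p@seed <- deriveSeed(masterSeed, r)
    members[[r]] <- tanaRun(p, nGenerations, J = J, ...)
  }
  horizon <- min(vapply(members, function(m) length(m@totals), integer(1)))
  new("TanaEnsemble", members = members, horizon = as.integer(horizon),
      masterSeed = as.numeric(masterSeed), sharedJ = sharedJ)
}

#' @describeIn tanaEnsemble Member trajectories (list).
#' @param ens a \code{TanaEnsemble}.
#' @param dropExtinct logical, drop members that terminated early.
#' @export
ensembleMembers <- function(ens, dropExtinct = TRUE) {
  m <- ens@members
  if (dropExtinct) {
    ext <- vapply(m, function(x) x@terminatedEarly, logical(1))
    if (any(ext))
      message(sum(ext), " extinct run(s) excluded from ensemble statistics")
    m <- m[!ext]
  }
  m
}

#' @describeIn tanaEnsemble Common horizon (generations).
#' @export
ensembleHorizon <- function(ens) ens@horizon

setMethod("show", "TanaEnsemble", function(object) {
  ext <- sum(vapply(object@members, function(x) x@terminatedEarly,
                    logical(1)))
  cat("TanaEnsemble:", length(object@members), "runs x", object@horizon,
      "generations, pMut =", object@members[[1]]@params@pMut,
      if (ext) sprintf("(%d extinct)", ext) else "", "\n")
})
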