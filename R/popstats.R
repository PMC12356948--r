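#' Hill diversity of a population distribution
#'
#' The exponential of the Shannon index (natural log) of the normalized
#' population distribution: the effective number of species.  Equals the
#' number of occupied species for a uniform distribution and 1 when a
#' single species holds the whole population.
#'
#' @param populations non-negative counts (zeros ignored).
#' @return Hill diversity in \code{[1, number of occupied species]}.
#' @examples
#' hillDiversity(rep(10, 8))   # 8
#' hillDiversity(c(2, 1, 1))   # exp(1.5 * log(2))
#' @export
hillDiversity <- function(populations) {
  p <- populations[populations > 0]
  if (!length(p)) stop("all-zero population: diversity undefined")
  p <- p / sum(p)
  exp(-sum(p * log(p)))
}

#' Normalized Shannon entropy of a population distribution
#'
#' Shannon entropy (natural log) of the normalized counts divided by the
#' log of the number of occupied species, so 1 means a perfectly uniform
#' distribution.  Defined as 0 when exactly one species is occupied.
#'
#' @param populations non-negative counts (zeros ignored).
#' @return Entropy in \code{[0, 1]}.
#' @examples
#' normalizedEntropy(c(5, 5, 5))  # 1
#' normalizedEntropy(c(2, 1, 1))  # ~0.9464
#' @export
normalizedEntropy <- function(populations) {
  p <- populations[populations > 0]
  if (!length(p)) stop("all-zero population: entropy undefined")
  if (length(p) == 1L) return(0)
  p <- p / sum(p)
  -sum(p * log(p)) / log(length(p))
}

# per-generation list of core sets (species with count >= occupancy
# threshold) from a trajectory's sparse records
.coreSets <- function(traj, occupancyMin, occupancyFrac) {
  rec <- traj@records
  thr <- pmax(occupancyMin, occupancyFrac * traj@totals)
  keep <- rec$count >= thr[rec$generation]
  split(rec$speciesId[keep], factor(rec$generation[keep],
                                    levels = seq_along(traj@totals)))
}

.jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(0)  # no stable core: not metastable
  u <- length(union(a, b))
  if (u == 0L) 0 else length(intersect(a, b)) / u
}

#' Segment a trajectory into q-ESS and reorganization epochs
#'
#' Detector for quasi-evolutionary-stable states: per generation, the
#' "core set" is the set of species whose count reaches
#' \code{max(occupancyMin, occupancyFrac * N(t))}.  Consecutive
#' generations whose core sets have Jaccard similarity at least
#' \code{jaccardThreshold} are chained; maximal chains of at least
#' \code{minLength} generations are labeled \code{qess}, everything else
#' \code{reorg}.  Two consecutive empty core sets are treated as
#' dissimilar (no stable core is not a metastable state).
#'
#' @param traj a \linkS4class{TanaTrajectory}.
#' @param occupancyMin,occupancyFrac absolute floor and fraction of
#'   \code{N(t)} defining the core-set occupancy threshold.
#' @param jaccardThreshold similarity required to chain two generations.
#' @param minLength minimum q-ESS segment length in generations.
#' @return A \linkS4class{QessSegmentation}.
#' @examples
#' tr <- tanaRun(tanaParams(pMut = 0.005, seed = 3), nGenerations = 300)
#' seg <- segmentQess(tr)
#' reorgFraction(seg)
#' @export
segmentQess <- function(traj, occupancyMin = 5, occupancyFrac = 0.05,
                        jaccardThreshold = 0.8, minLength = 10L) {
  G <- length(traj@totals)
  if (G < minLength) stop("trajectory shorter than the minimum segment length")
  cores <- .coreSets(traj, occupancyMin, occupancyFrac)
  sim <- vapply(seq_len(G - 1L),
                function(g) .jaccard(cores[[g]], cores[[g + 1L]]),
                numeric(1))
  linked <- sim >= jaccardThreshold
  # maximal runs of linked consecutive generations: a run of m linked
  # links spans m + 1 generations and, if long enough, is one q-ESS
  # segment; distinct chains stay distinct segments even when adjacent
  # (a broken link marks a reorganization event between two epochs)
  r <- rle(linked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  chains <- which(r$values & r$lengths + 1L >= minLength)
  segs <- data.frame(start = integer(0), end = integer(0),
                     label = character(0), stringsAsFactors = FALSE)
  cursor <- 1L
  for (i in chains) {
    s <- starts[i]
    e <- ends[i] + 1L
    if (s > cursor)
      segs <- rbind(segs, data.frame(start = cursor, end = s - 1L,
                                     label = "reorg"))
    segs <- rbind(segs, data.frame(start = s, end = e, label = "qess"))
    cursor <- e + 1L
  }
  if (cursor <= G)
    segs <- rbind(segs, data.frame(start = cursor, end = G,
                                   label = "reorg"))
  new("QessSegmentation", segments = segs,
      detector = list(occupancyMin = occupancyMin,
                      occupancyFrac = occupancyFrac,
                      jaccardThreshold = jaccardThreshold,
                      minLength = as.integer(minLength)))
}

#' @describeIn segmentQess Fraction of analyzed generations labeled
#'   \code{reorg}.
#' @param seg a \code{QessSegmentation}.
#' @export
reorgFraction <- function(seg) {
  s <- seg@segments
  if (!nrow(s)) stop("empty segmentation")
  len <- s$end - s$start + 1L
  sum(len[s$label == "reorg"]) / sum(len)
}

#' @describeIn segmentQess Number of q-ESS segments.
#' @export
nQessSegments <- function(seg) sum(seg@segments$label == "qess")

setMethod("show", "QessSegmentation", function(object) {
  s <- object@segments
  cat("QessSegmentation:", nrow(s), "segments over",
      if (nrow(s)) max(s$end) else 0, "generations;",
      sprintf("reorg fraction %.3f", reorgFraction(object)), "\n")
})

#' Default burn-in rule
#'
#' The first 10\% of recorded generations, capped at 1000, are excluded
#' from all stationary-regime summary statistics; the initial transient
#' from the arbitrary initial condition is not part of the regime the
#' population figures describe.
#'
#' @param nGenerations trajectory length in generations.
#' @return Number of generations to discard.
#' @examples
#' burnIn(2000)   # 200
#' burnIn(50000)  # 1000
#' @export
burnIn <- function(nGenerations) {
  min(1000L, as.integer(floor(0.1 * nGenerations)))
}

# per-generation summary statistics of a single run (post burn-in)
.trajStats <- function(traj, burn = burnIn(length(traj@totals))) {
  G <- length(traj@totals)
  keep <- (burn + 1L):G
  rec <- traj@records
  dt <- data.table::as.data.table(rec)[generation %in% keep]
  st <- dt[, .(hill = hillDiversity(count),
               entropy = normalizedEntropy(count)),
           by = generation]
  list(generations = keep, totals = traj@totals[keep],
       hill = st$hill[match(keep, st$generation)],
       entropy = st$entropy[match(keep, st$generation)])
}

#' Population-statistics sweep over mutation rates
#'
#' Simulates an ensemble at every mutation rate of the grid and reports
#' ensemble means and standard deviations (across runs, of each run's
#' post-burn-in time average) of the total population, Hill diversity,
#' normalized entropy and the reorganization fraction of the default
#' q-ESS detector.  Runs are simulated and summarized one at a time so
#' memory stays flat; extinct runs are excluded and counted.
#'
#' @param pMutGrid mutation-rate grid (non-empty).
#' @param nRuns runs per rate.
#' @param nGenerations generations per run.
#' @param masterSeed master seed; per-(rate, run) seeds are derived.
#' @param params base \linkS4class{TanaParams} (its \code{pMut} and
#'   \code{seed} are overridden).
#' @param detector list of \code{\link{segmentQess}} parameter overrides.
#' @param ... further arguments passed to \code{\link{tanaRun}} (e.g.
#'   \code{neutral}).
#' @return A data.frame with one row per rate: mean/sd of each statistic,
#'   the number of non-extinct runs, and the analysis window.
#' @examples
#' \donttest{
#' sweepPopstats(c(0.01, 0.05), nRuns = 4, nGenerations = 500,
#'               masterSeed = 11)
#' }
#' @export
sweepPopstats <- function(pMutGrid, nRuns, nGenerations, masterSeed = 1,
                          params = tanaParams(), detector = list(), ...) {
  stopifnot(length(pMutGrid) >= 1)
  out <- vector("list", length(pMutGrid))
  for (gi in seq_along(pMutGrid)) {
    pm <- pMutGrid[gi]
    N <- hill <- ent <- reorg <- numeric(0)
    nExt <- 0L
    for (r in seq_len(nRuns)) {
      p <- params
      p@pMut <- pm
      p@seed <- deriveSeed(masterSeed, gi * 100003L + r)
      tr <- tanaRun(p, nGenerations, ...)
      if (tr@terminatedEarly) { nExt <- nExt + 1L; next }
      st <- .trajStats(tr)
      seg <- do.call(segmentQess, c(list(tr), detector))
      # reorg fraction over the post-burn-in window
      lab <- rep(seg@segments$label, seg@segments$end - seg@segments$start + 1L)
      N <- c(N, mean(st$totals))
      hill <- c(hill, mean(st$hill))
      ent <- c(ent, mean(st$entropy))
      reorg <- c(reorg, mean(lab[st$generations] == "reorg"))
    }
    out[[gi]] <- data.frame(
      pMut = pm,
      meanN = mean(N), sdN = sd(N),
      meanHill = mean(hill), sdHill = sd(hill),
      meanEntropy = mean(ent), sdEntropy = sd(ent),
      meanReorg = mean(reorg), sdReorg = sd(reorg),
      nRuns = length(N), nExtinct = nExt,
      windowStart = burnIn(nGenerations) + 1L,
      windowEnd = nGenerations)
  }
  do.call(rbind, out)
}
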