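# ---- Transfer entropy and integrated information ----

#' Transfer entropy between ensemble-aligned series
#'
#' \eqn{TE(S \to E) = I(S(t); E(t+1) \mid E(t))}: the information the
#' source's present adds about the target's future beyond the target's
#' own present (first-order Markov condition).  Directional; the source
#' may be multivariate (e.g. a 6-species group).  Estimated across the
#' ensemble at each generation and averaged over the window.
#'
#' @param source array \code{[run, time, vars]} or matrix
#'   \code{[run, time]} of the source variable(s).
#' @param target matrix \code{[run, time]} (or 3-d array with one
#'   variable) of the target.
#' @param window generations \code{t} to average over.
#' @param stride keep every \code{stride}-th generation.
#' @return List with \code{mean} (nats, >= 0), \code{sd}, \code{nTimes},
#'   \code{values}.
#' @examples
#' x <- matrix(rnorm(200 * 30), 200, 30)
#' y <- matrix(rnorm(200 * 30), 200, 30)
#' transferEntropy(x, y, window = 1:29)$mean  # ~ 0, independent series
#' @export
transferEntropy <- function(source, target, window, stride = 1L) {
  as3d <- function(x) if (length(dim(x)) == 3L) x
                      else array(x, c(dim(x), 1L))
  src <- as3d(source)
  tgt <- as3d(target)
  stopifnot(dim(src)[1] == dim(tgt)[1], dim(src)[2] == dim(tgt)[2])
  if (max(window) + 1L > dim(tgt)[2])
    stop("window extends past the horizon (t + 1 needed)")
  nRuns <- dim(src)[1]
  dS <- dim(src)[3]
  dT <- dim(tgt)[3]
  .refuse(nRuns, dS + 2L * dT)
  slice <- function(a, t) {
    x <- a[, t, , drop = FALSE]
    dim(x) <- c(dim(a)[1], dim(a)[3])
    x
  }
  ts <- window[seq(1L, length(window), by = stride)]
  vals <- vapply(ts, function(t) {
    gaussianCMI(slice(src, t), slice(tgt, t + 1L), slice(tgt, t))
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       nTimes = length(vals), values = vals)
}

# all terms of the whole-minus-sum decomposition of a 2-part system from
# one joint ridged covariance of (X1(t), X2(t), X1(t+1), X2(t+1))
.phiTerms <- function(x1, x2, t) {
  S <- cbind(x1[, t], x2[, t], x1[, t + 1L], x2[, t + 1L])
  C <- .ridged(cov(S))
  mi <- function(ix, iy)
    max(0, 0.5 * (.logdet(C, ix) + .logdet(C, iy) - .logdet(C, c(ix, iy))))
  joint <- mi(1:2, 3:4)
  self1 <- mi(1L, 3L)
  self2 <- mi(2L, 4L)
  # lagged MI for every ordered pair (i, j), self-pairs included
  pair <- c(mi(1L, 3L), mi(1L, 4L), mi(2L, 3L), mi(2L, 4L))
  list(wms = joint - self1 - self2, minPair = min(pair))
}

#' Whole-minus-sum integrated information of a 2-part system
#'
#' \eqn{\Phi^{WMS} = I(\mathbf{X}(t); \mathbf{X}(t+1)) - \sum_i
#' I(X_i(t); X_i(t+1))}: the excess self-prediction of the joint system
#' over its parts taken separately.  Can be negative when the parts are
#' highly correlated (redundancy is double-counted); see
#' \code{\link{phiR}} for the redundancy-corrected revision.
#'
#' @param x1,x2 matrices \code{[run, time]}, the two parts.
#' @param window generations \code{t} to average over.
#' @param stride keep every \code{stride}-th generation.
#' @return List with \code{mean} (nats, may be negative), \code{sd},
#'   \code{nTimes}, \code{values}.
#' @export
phiWMS <- function(x1, x2, window, stride = 1L) {
  .phiEngine(x1, x2, window, stride, function(tt) tt$wms)
}

#' Revised integrated information of a 2-part system
#'
#' \eqn{\Phi^{R} = \Phi^{WMS} + \min_{i,j} I(X_i(t); X_j(t+1))}: the
#' whole-minus-sum measure plus the minimum lagged mutual information
#' over all ordered part pairs (self-pairs included), which restores the
#' redundancy subtracted twice by \eqn{\Phi^{WMS}}.  Always at least
#' \eqn{\Phi^{WMS}}.
#'
#' @inheritParams phiWMS
#' @return List as in \code{\link{phiWMS}}.
#' @export
phiR <- function(x1, x2, window, stride = 1L) {
  .phiEngine(x1, x2, window, stride, function(tt) tt$wms + tt$minPair)
}

.phiEngine <- function(x1, x2, window, stride, pick) {
  stopifnot(all(dim(x1) == dim(x2)))
  if (max(window) + 1L > ncol(x1))
    stop("window extends past the horizon (t + 1 needed)")
  .refuse(nrow(x1), 4L)
  ts <- window[seq(1L, length(window), by = stride)]
  vals <- vapply(ts, function(t) pick(.phiTerms(x1, x2, t)), numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       nTimes = length(vals), values = vals)
}

#' Species-environment information profile
#'
#' Characterizes species-environment interaction at a given scale:
#' transfer entropy in both directions between the group's joint
#' population and the scalar environment population
#' \code{E(t) = N(t) - sum(group)}, plus (at scale 1 only, where the
#' species-environment pair is a 2-part system) the integrated
#' information measures \eqn{\Phi^{WMS}} and \eqn{\Phi^{R}}.  At scale 1
#' the measures are averaged over the \code{nTop} top-ranked species; at
#' higher scales the single top group of ranks \code{1..scale} is used.
#'
#' @param ra rank-aligned arrays from \code{\link{rankAlign}}.
#' @param scale group size (1 for single species; 6 is the higher-order
#'   scale of interest).
#' @param nTop number of top-ranked species averaged over at scale 1.
#' @param window generations \code{t} to average over.
#' @param stride time stride.
#' @return data.frame with one row per measure: \code{measure},
#'   \code{direction}, \code{scale}, \code{value} (nats), \code{sd},
#'   \code{nUnits} (species averaged over).
#' @export
speciesEnvironmentProfile <- function(ra, scale = 1L, nTop = 6L,
                                      window = ra$window, stride = 1L) {
  window <- window[window + 1L <= dim(ra$pops)[2]]
  if (scale == 1L) {
    units <- seq_len(min(nTop, dim(ra$pops)[3]))
    acc <- lapply(units, function(r) {
      x <- ra$pops[, , r]
      E <- ra$totals - x
      if (any(E < 0)) stop("rank series exceeds the total population")
      list(se = transferEntropy(x, E, window, stride)$mean,
           es = transferEntropy(E, x, window, stride)$mean,
           wms = phiWMS(x, E, window, stride)$mean,
           pr = phiR(x, E, window, stride)$mean)
    })
    get <- function(f) vapply(acc, `[[`, numeric(1), f)
    data.frame(
      measure = c("TE", "TE", "phiWMS", "phiR"),
      direction = c("S->E", "E->S", NA, NA),
      scale = 1L,
      value = c(mean(get("se")), mean(get("es")),
                mean(get("wms")), mean(get("pr"))),
      sd = c(sd(get("se")), sd(get("es")), sd(get("wms")), sd(get("pr"))),
      nUnits = length(units))
  } else {
    subset <- seq_len(scale)
    S <- ra$pops[, , subset, drop = FALSE]
    E <- ra$totals - apply(S, c(1, 2), sum)
    if (any(E < 0)) stop("group series exceeds the total population")
    data.frame(
      measure = c("TE", "TE"),
      direction = c("S->E", "E->S"),
      scale = as.integer(scale),
      value = c(transferEntropy(S, E, window, stride)$mean,
                transferEntropy(E, S, window, stride)$mean),
      sd = NA_real_, nUnits = 1L)
  }
}
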