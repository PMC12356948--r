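# ---- Gaussian information estimators computed across ensembles ----
#
# All estimators share one covariance path: a joint sample covariance with
# a small relative ridge (1e-9 * trace/dim added to every diagonal entry),
# log-determinants via Cholesky, and a degeneracy gate that rejects
# ridge-dominated estimates (a duplicated variable inflates the value to
# ~ 0.5*log(1/ridge) nats per shared dimension).  Units are nats (natural
# log) throughout; a bits conversion exists only at reporting.

.RIDGE_REL <- 1e-9
# estimates at or above this magnitude are ridge-dominated artefacts of a
# (near-)singular cross-block (e.g. MI of a variable with itself), not
# finite information values: 0.5 * log(1/ridge) ~ 10.4 nats, with margin
.MI_DEGENERATE <- 8

.asMat <- function(x) {
  if (is.null(x)) return(NULL)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

.ridged <- function(C) {
  d <- nrow(C)
  C + diag(.RIDGE_REL * sum(diag(C)) / d, d)
}

.checkBlock <- function(C, idx, name) {
  if (any(diag(C)[idx] <= 0))
    stop("degenerate covariance in block '", name, "': zero variance")
  invisible(TRUE)
}

.checkFinite <- function(value, name, dmin = 1L) {
  # a duplicated variable contributes ~ 0.5*log(1/ridge) nats, so the
  # divergence ceiling scales with the smaller block dimension
  if (!is.finite(value) || value >= .MI_DEGENERATE * dmin)
    stop("degenerate estimate for block '", name, "': the value (",
         format(value, digits = 3), " nats) is ridge-dominated, ",
         "indicating a (near-)duplicated variable across blocks")
  value
}

.logdet <- function(C, idx) {
  B <- C[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(B), error = function(e)
    stop("covariance block not positive definite after ridge"))
  2 * sum(log(diag(ch)))
}

# joint ridged covariance of the column-bound blocks; exactly constant
# columns are refused before the ridge can mask them
.jointCov <- function(...) {
  blocks <- Filter(Negate(is.null), list(...))
  C <- cov(do.call(cbind, blocks))
  if (any(diag(C) == 0))
    stop("degenerate covariance: zero variance (exactly constant column ",
         paste(which(diag(C) == 0), collapse = ", "), ")")
  .ridged(C)
}

#' Gaussian mutual information between two sample blocks
#'
#' Estimates \eqn{I(X; Y) = \frac12 \ln\frac{\det\Sigma_X\,\det\Sigma_Y}
#' {\det\Sigma_{XY}}} from the joint sample covariance, with a small
#' relative ridge on the diagonal for numerical stability, clamped at 0.
#' Rows are samples (here: ensemble members at a fixed generation),
#' columns are variables.
#'
#' @param X,Y numeric matrices (or vectors) with one row per sample.
#' @return Mutual information in nats (>= 0).
#' @examples
#' set.seed(1)
#' x <- rnorm(5000); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(5000)
#' gaussianMI(x, y)  # ~ -0.5 * log(1 - 0.81)
#' @export
gaussianMI <- function(X, Y) {
  X <- .asMat(X); Y <- .asMat(Y)
  n <- nrow(X)
  dx <- ncol(X); dy <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of samples")
  if (n <= dx + dy + 1L)
    stop("too few samples (", n, ") for joint dimension ", dx + dy)
  C <- .jointCov(X, Y)
  ix <- seq_len(dx); iy <- dx + seq_len(dy)
  .checkBlock(C, ix, "X"); .checkBlock(C, iy, "Y")
  v <- 0.5 * (.logdet(C, ix) + .logdet(C, iy) - .logdet(C, c(ix, iy)))
  max(0, .checkFinite(v, "[X,Y]", min(dx, dy)))
}

#' Gaussian conditional mutual information
#'
#' Estimates \eqn{I(X; Y \mid Z)} in one pass from the joint covariance of
#' \code{[X, Y, Z]} via
#' \eqn{\frac12 \ln \frac{\det\Sigma_{XZ}\,\det\Sigma_{YZ}}
#' {\det\Sigma_Z\,\det\Sigma_{XYZ}}}, clamped at 0.  With \code{Z = NULL}
#' this is plain \code{\link{gaussianMI}}.
#'
#' @param X,Y,Z numeric matrices (or vectors) with one row per sample;
#'   \code{Z} may be \code{NULL}.
#' @return Conditional mutual information in nats (>= 0).
#' @examples
#' set.seed(1)
#' z <- rnorm(5000); x <- z + rnorm(5000); y <- z + rnorm(5000)
#' gaussianCMI(x, y, z)  # ~ 0: dependence is through z only
#' @export
gaussianCMI <- function(X, Y, Z = NULL) {
  if (is.null(Z) || (!is.null(dim(Z)) && ncol(as.matrix(Z)) == 0L))
    return(gaussianMI(X, Y))
  X <- .asMat(X); Y <- .asMat(Y); Z <- .asMat(Z)
  n <- nrow(X)
  if (nrow(Y) != n || nrow(Z) != n)
    stop("X, Y, Z must have the same number of samples")
  dx <- ncol(X); dy <- ncol(Y); dz <- ncol(Z)
  if (n <= dx + dy + dz + 1L)
    stop("too few samples (", n, ") for joint dimension ", dx + dy + dz)
  C <- .jointCov(X, Y, Z)
  ix <- seq_len(dx); iy <- dx + seq_len(dy); iz <- dx + dy + seq_len(dz)
  .checkBlock(C, c(ix, iz), "[X,Z]"); .checkBlock(C, c(iy, iz), "[Y,Z]")
  v <- 0.5 * (.logdet(C, c(ix, iz)) + .logdet(C, c(iy, iz)) -
                .logdet(C, iz) - .logdet(C, c(ix, iy, iz)))
  max(0, .checkFinite(v, "[X,Y|Z]", min(dx, dy)))
}

#' Convert nats to bits
#'
#' Reporting-layer convenience; every estimator in the package works in
#' nats.
#'
#' @param x value(s) in nats.
#' @return Value(s) in bits.
#' @examples
#' natsToBits(log(2))  # 1
#' @export
natsToBits <- function(x) x / log(2)

# minimum ensemble-size / joint-dimension ratio below which estimates are
# refused rather than silently reported
.MIN_ENSEMBLE_RATIO <- 10

.refuse <- function(n, dim, ratio = .MIN_ENSEMBLE_RATIO) {
  if (n < ratio * dim)
    stop(errorCondition(
      sprintf(paste0("ensemble size %d is below %g x joint dimension %d; ",
                     "estimate refused"), n, ratio, dim),
      class = c("tana_refusal", "error", "condition")))
  invisible(TRUE)
}

#' Time-averaged ensemble information measure
#'
#' The estimation backbone for non-stationary dynamics: at every
#' generation \code{t} of the window, the cross-ensemble sample of the
#' extracted variables at \code{t} (and \code{t + 1}) is formed and the
#' measure applied; the per-generation estimates are then averaged.  The
#' ensemble must exceed the joint dimension by a safety factor
#' (default 10), otherwise the estimate is refused with an error of class
#' \code{tana_refusal}.
#'
#' @param arr numeric array \code{[run, time, variable]}.
#' @param measure function \code{(Xt, Xt1)} of the cross-ensemble sample
#'   matrices at \code{t} and \code{t + 1}, returning one number; for
#'   measures that do not need the lead sample, ignore the second
#'   argument.
#' @param vars variable (third-dimension) indices entering the sample.
#' @param window generation indices \code{t} to average over; \code{t + 1}
#'   must stay within the array.
#' @param jointDim joint dimension used for the ensemble-size check.
#' @param stride keep every \code{stride}-th generation of the window.
#' @return List with \code{mean}, \code{sd} (across generations),
#'   \code{nTimes} and the per-generation \code{values}.
#' @examples
#' arr <- array(rnorm(200 * 20 * 2), c(200, 20, 2))
#' ensembleMeasure(arr, function(Xt, Xt1) gaussianMI(Xt, Xt1),
#'                 vars = 1:2, window = 1:19)$mean  # ~ 0
#' @export
ensembleMeasure <- function(arr, measure, vars, window,
                            jointDim = 2L * length(vars), stride = 1L) {
  stopifnot(length(dim(arr)) == 3L, length(window) >= 1L)
  if (max(window) + 1L > dim(arr)[2])
    stop("window extends past the array horizon (t + 1 needed)")
  .refuse(dim(arr)[1], jointDim)
  ts <- window[seq(1L, length(window), by = stride)]
  vals <- vapply(ts, function(t) {
    Xt <- arr[, t, vars, drop = FALSE]
    Xt1 <- arr[, t + 1L, vars, drop = FALSE]
    dim(Xt) <- c(dim(arr)[1], length(vars))
    dim(Xt1) <- c(dim(arr)[1], length(vars))
    measure(Xt, Xt1)
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       nTimes = length(vals), values = vals)
}
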