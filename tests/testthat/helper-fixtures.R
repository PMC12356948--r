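# Shared fixture builders: synthetic trajectories with known structure and
# small cached simulation objects reused across test files.

# build a TanaTrajectory directly from a generation -> (speciesId, count)
# description; `comp` is a list of named integer vectors, one per generation
makeTrajectory <- function(comp, pMut = 0.01) {
  recs <- do.call(rbind, lapply(seq_along(comp), function(g) {
    data.frame(generation = g,
               speciesId = as.integer(names(comp[[g]])),
               count = as.integer(comp[[g]]))
  }))
  new("TanaTrajectory", params = tanaParams(pMut = pMut, seed = 1),
      records = recs,
      totals = vapply(comp, function(x) as.integer(sum(x)), integer(1)),
      terminatedEarly = FALSE, seedRun = 0, seedJ = 0, neutral = FALSE)
}

# constant composition for n generations
constantComp <- function(n, pops = c("1" = 50L, "2" = 30L, "3" = 20L)) {
  replicate(n, pops, simplify = FALSE)
}

# per-generation pairwise-disjoint compositions (every core set disjoint
# from the previous one)
churnComp <- function(n, perGen = 3L) {
  lapply(seq_len(n), function(g) {
    ids <- as.character(((g - 1L) * perGen):((g * perGen) - 1L))
    stats::setNames(rep(20L, perGen), ids)
  })
}

# zero-interaction matrix (useful for deterministic fitness arithmetic)
zeroInteraction <- function(L = 10L) {
  new("TanaInteraction", weights = matrix(0, 2^L, 2^L), neutral = FALSE,
      pairwise = FALSE, seed = 0)
}

# interaction matrix with chosen entries set; `entries` is a data.frame
# with columns i, j, w (0-based species ids)
customInteraction <- function(entries, L = 10L) {
  W <- matrix(0, 2^L, 2^L)
  for (r in seq_len(nrow(entries)))
    W[entries$i[r] + 1L, entries$j[r] + 1L] <- entries$w[r]
  new("TanaInteraction", weights = W, neutral = FALSE, pairwise = FALSE,
      seed = 0)
}

# cross-ensemble samples of a bivariate Gaussian with given correlation
bivariateSample <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}

# independent-path Gaussian MI from a sample: explicit covariance
# determinants, no shared code with the package estimator
bruteForceMI <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ridge <- function(C) C + diag(1e-9 * sum(diag(C)) / nrow(C), nrow(C))
  C <- ridge(stats::cov(cbind(X, Y)))
  ix <- seq_len(ncol(X)); iy <- ncol(X) + seq_len(ncol(Y))
  dt <- function(i) det(C[i, i, drop = FALSE])
  0.5 * log(dt(ix) * dt(iy) / dt(c(ix, iy)))
}
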