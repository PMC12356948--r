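---
title: "Co-evolutionary dynamics and information-theoretic individuality in the Tangled Nature model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-evolutionary dynamics and information-theoretic individuality in the Tangled Nature model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

The Tangled Nature model evolves a population of asexually reproducing
agents.  Each agent belongs to a species identified by a binary pangenome
of `L` bits, so there are `M = 2^L` possible species; with the standard
`L = 10` used throughout this package, `M = 1024`.  Species interact
through a random web `J`: each directed entry `J[i, j]` is permitted with
probability `theta` and, if permitted, drawn Uniform(-1, 1).  `J[i, j]`
is the per-capita influence of species `j` on the fitness of species
`i`:

    H_i(t) = (k / N(t)) * sum_j J[i, j] * n_j(t)  -  mu * N(t)

where `n_j(t)` are species populations, `N(t)` their total, `k` scales
interaction strength and `mu` is the inverse carrying capacity — the
resource constraint that penalizes total population growth.  Fitness
maps to a reproduction probability through a logistic link
`p_off = 1 / (1 + exp(-H))`, so even maladapted species keep a small
chance to reproduce and mutate toward fitter genomes.

An elementary timestep is: (a) with probability `pKill` one uniformly
chosen individual dies; (b) one uniformly chosen individual reproduces
with probability `p_off` of its species.  Both selections are uniform
over *individuals*, i.e. population-weighted over species.  A
*generation* is `round(N(t) / pKill)` timesteps — the expected time to
turn over the entire population — and the state is recorded once per
generation.

## Reproduction scheme

Two reproduction variants are implemented, selected by the `scheme`
field of `tanaParams()`:

* **`"replace"` (default)** — a reproducing parent is replaced by two
  copies, each genome bit of each copy flipping independently with
  probability `pMut`.  This is the classical formulation of the model.
  Because the parent's own lineage is re-drawn at every reproduction,
  every lineage carries the full mutation load, and a simple balance
  argument locates the error threshold: a wild type persists only while
  `p_off * (1 - 2q) > pKill` with `q = 1 - (1 - pMut)^L` the
  per-genome mutation probability.  At `p_off` near 1 (a strongly
  mutualistic community), `pKill = 0.2` and `L = 10` this gives
  `pMut ≈ 0.05` — the threshold the mutation-rate sweep exhibits.
* **`"budding"`** — the parent is retained and a single mutated
  offspring is added.  Here the parent genotype is never re-drawn, the
  mutation load per lineage is roughly halved and the error threshold
  moves far above 0.1: metastable states survive at mutation rates
  where the replacement scheme has long since dissolved into a mutation
  cloud.  We keep this variant because the timestep is often described
  this way in summaries of the model, and the contrast between the two
  schemes is itself instructive.

We chose `"replace"` as the default because only it reproduces the
canonical mutation-rate phenomenology (monotone population decline with
a collapse after `pMut ≈ 0.03–0.04` at the scales we simulate, loss of
metastability approaching 0.05, near-uniform population distributions
beyond).

Both schemes keep the per-timestep population change in {-1, 0, +1},
and both are exposed through the pure-R reference timestep `tanaStep()`
whose random draws can be injected for contract testing; production
runs use a compiled loop (~1 ms per generation at `N ≈ 1500` on one
core) with a self-contained xoshiro256** generator, so trajectories
are bit-reproducible from `(params, seed)` across platforms.

## Initial condition and other defaults

Runs start from `n0 = 500` individuals spread uniformly over
`n0Species = 10` distinct uniformly chosen species — a "random initial
condition where only a subset of species exists".  The coupling mask is
drawn independently per directed entry by default (`J[i, j]` may be
permitted while `J[j, i]` is not); a `pairwise` switch draws one coin
per unordered pair instead, since the literature varies on this point.
Self-interactions are excluded (`J[i, i] = 0`): the fitness sum is over
influences from *other* species, and a nonzero diagonal would act as an
uncontrolled self-amplification term.  The neutral control replaces
every permitted weight by one constant (default 0.1, which puts the
neutral equilibrium population near `k * w / mu ≈ 470`): in it, no
interaction *structure* exists to be selected, which is the relevant
null for higher-order individuality.

In ensembles, every run by default redraws its own interaction matrix
and initial condition from counter-derived seeds (`sharedJ = TRUE`
shares one matrix).  Rank alignment (below) makes the cross-run
variables comparable in either mode; in our reduced-scale experiments
the two modes gave qualitatively identical information profiles, so the
more conservative independent-matrix default was kept.  Extinct runs
are flagged and excluded from ensemble statistics (the estimators need
non-degenerate populations); the exclusion is logged by the accessors.

# Population statistics and metastability

Diversity is the exponential of the Shannon index of the normalized
population distribution (Hill diversity, natural logs): the effective
number of species.  The normalized entropy divides the Shannon index by
`log` of the number of occupied species, so 1 means uniformity; it is
defined as 0 for a single occupied species.  Both are computed per
recorded generation and averaged over a post-burn-in window; the
burn-in is the first 10% of generations, capped at 1000.

Quasi-evolutionary-stable states (q-ESS) — epochs during which a fixed
core of abundant species persists — are detected by a rule of our own
construction, since the underlying studies use but do not define a
detector.  Per generation the *core set* is every species with count at
least `max(5, 0.05 * N(t))`; consecutive generations whose core sets
have Jaccard similarity at least 0.8 are chained; chains spanning at
least 10 generations are q-ESS segments, everything else is
reorganization.  Two adjacent chains remain distinct segments (the
broken link between them is precisely a reorganization event), and two
consecutive *empty* core sets count as dissimilar — a system with no
stable core is not metastable.  All three thresholds are exposed as
arguments; the reorganization fraction is monotone in the similarity
threshold, which the test suite asserts.  Quantities that depend on
this detector (the reorganization-fraction crossing, the rate at which
metastability vanishes) should be read as detector-relative.

# Ensemble information estimation

The model is non-stationary — the population distribution drifts
through metastable epochs — so information measures are estimated
*across the ensemble*: at each generation `t` the cross-run sample of
the variables at `t` (and `t + 1`) forms the empirical distribution,
the measure is computed per `t`, and the per-generation values are
averaged over the window.  All estimators are Gaussian: mutual
information and conditional mutual information are covariance
log-determinant expressions, evaluated from one joint sample covariance
with a relative ridge of `1e-9 * trace/dim` on the diagonal (population
counts can be locally degenerate).  Counts are treated as continuous;
no discretization is applied.  Units are nats everywhere;
`natsToBits()` exists for reporting only.

Three guards make estimates refuse rather than mislead:

* fewer samples than joint dimension + 2 is an error;
* ensemble size below 10 times the joint dimension raises a refusal
  condition (`tana_refusal`) that sweep tables surface as `NA` rows with
  a reason, never silently drop;
* ridge-dominated values (at least ~8 nats per shared dimension, the
  signature of a variable duplicated across blocks, e.g. the MI of a
  variable with itself) raise a degeneracy error naming the block.

The estimators are validated against stationary VAR(1) fixtures
(`simulateVAR()`, `plantedBlockEnsemble()`) whose exact information
values follow from the discrete Lyapunov equation
(`stationaryCov()`, `analyticInfo()`).  Fixtures are genuinely
continuous Gaussian processes — the model under which the estimators
are exact — so closed-form ground truth is available; count-likeness
(positive, ordered magnitudes) is emulated only by affine shifts, which
no information measure can see.  What fixtures do *not* emulate is the
TaNa model's non-stationary epoch structure; passing the fixture suite
therefore certifies the estimators, not the ecological conclusions.

# Individuality measures

For a group `S(t)` of `K` species populations with environment
`E(t) = N(t) - sum(S(t))` (the informational complement, a scalar):

* organismal individuality `A* = I(S(t); S(t+1))` — the group's
  self-prediction;
* colonial individuality `A = I(S(t); S(t+1) | E(t))`;
* environment-determined individuality
  `nC = I(E(t); S(t+1) | S(t))`, identically the transfer entropy
  from environment to group.

Species identities are not comparable across runs, so groups are formed
over *population ranks*: within each run, species are ranked by
time-averaged population over the window (ties by ascending species
id), fixed once per run — not re-ranked per generation, which would
inject label-switching noise into the lag-1 measures.  This rank
alignment is this package's mechanism for making cross-ensemble joint
distributions well defined; it is a design choice, and scores should be
read as properties of rank-aligned groups.

Scale-`K` subsets of ranks are enumerated best-first in non-increasing
order of summed rank mass (exactly; a heap-based enumeration with
lexicographic tie-breaks, validated against brute force), truncated at
a configurable limit.  The normalized score is `A*/K`.  When comparing
scales, `scaleSweep()` additionally subtracts the first-order
small-sample bias of the Gaussian MI estimate (`K^2 / 2n` nats, i.e.
`K / 2n` per species at ensemble size `n`) before taking the argmax,
and treats scores within `tieTol` (default 0.005 nats/species) of the
maximum as tied, resolving toward the smaller scale.  Without the bias
adjustment, structureless data would systematically report the largest
scale as optimal, purely because estimator bias grows with dimension.

Transfer entropy `TE(S -> E) = I(S(t); E(t+1) | E(t))` (first-order
Markov condition) supports multivariate sources and targets.  The
integrated-information measures for the 2-part system
`X = (species, environment)` are the whole-minus-sum
`Phi_WMS = I(X(t); X(t+1)) - sum_i I(X_i(t); X_i(t+1))`, which can be
negative for strongly correlated parts, and the revised
`Phi_R = Phi_WMS + min over ordered pairs (i, j) of
I(X_i(t); X_j(t+1))`.  The minimum runs over all ordered pairs
including `i = j`, the literal reading of the defining expression; a
cross-pairs-only variant would only raise `Phi_R`, and the identity
`Phi_R - Phi_WMS = min pairwise lagged MI >= 0` holds exactly on any
input, which the tests assert.  Phi profiles are computed for (single
species, environment) pairs and averaged over the top six ranked
species by default (`nTop`), matching the single-species-level
convention of the integrated-information analysis.

# Problem sizes and what reduced scale shows

The full-scale study design (10,000 runs of 100,000 generations per
mutation rate) is the reference point, not something this package runs
by default.  The bundled analyses and acceptance checks use
desk-scale ensembles chosen as the package's own working sizes:
24 runs x 3000 generations per rate for the population sweep, 20 x 2000
for metastability loss, 50 x 2000 for the entropy level, 150 x 900 for
the individuality crossover and 60 x 500 for the integration profile.

At these sizes the simulated ecosystems are *young*: q-ESS epochs are
shorter, interaction webs have had little time to evolve toward the
strongly mutualistic cliques that mature communities develop, and the
effective error threshold sits slightly below its asymptotic location
(the collapse happens around 0.03-0.04 rather than after 0.04, because
`p_off` has not yet been driven toward 1).  Consequences we observe and
report as scale effects rather than hiding:

* the Hill-diversity maximum tends to sit at the top of the swept grid
  (the high-rate mutation cloud is the most diverse state a young
  system reaches) instead of at 0.04;
* the reorganization fraction crosses one half at lower rates than a
  mature system would show;
* higher-order individuality above scale 2 does not dominate at low
  mutation rates — scale 2 is typically optimal there, and the
  characteristic advantage of scales 5-6 over scale 1 is not yet
  established, although the *loss* of higher-order individuality in
  the transition region (optimal scale 1 at 0.042-0.045, with the
  scale-1 score overtaking scale 6) reproduces clearly.

The parameter-recovery suite (planted VAR blocks of size 1, 3 and 6
recovered by `scaleSweep` across seeds) shows the estimation machinery
itself resolves group structure correctly at these ensemble sizes; the
missing low-rate higher-order structure is an ecological scale effect,
not an estimator failure.

# Numerical choices

* Natural logarithms throughout; diversity and entropy per generation;
  means over runs of per-run time means, standard deviations across
  runs.
* Ridge `1e-9 * trace/dim`; MI/CMI clamped at zero (phi measures are
  not clamped — their sign is informative).
* Ensemble/dimension safety ratio 10; refusals are first-class results.
* Rank ties break by ascending species id; subset-enumeration ties
  break lexicographically; optimal-scale ties break toward the smaller
  scale within 0.005 nats/species.
* Seeds: one master seed per experiment; every stream (per run, per
  interaction matrix, per stage) is derived by a counter-based
  splitmix64 expansion and recorded in trajectory objects and the
  pipeline manifest.
* Generation length `max(1, round(N/pKill))` uses `N` at the
  generation's start; extinction inside a generation terminates the run
  with `terminatedEarly` set.

# Known limitations

The Gaussian model ignores the discreteness and skewness of count
distributions; at high mutation rates many rank series are small
counts, where Gaussian MI is a biased (though monotone) proxy.  The
q-ESS detector is a stand-in for an undefined criterion and all
detector-relative quantities inherit its thresholds.  Desk-scale
ensembles understate higher-order organization for the reasons above;
the pipeline accepts arbitrary `nRuns`/`nGenerations` for users with
more compute budget.
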