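Package: TangledNature
Title: Tangled Nature Co-Evolution Model and Ensemble Information Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic simulation of the Tangled Nature model of
    co-evolving species, together with ensemble information-theoretic
    analysis of the resulting population dynamics: population diversity
    and quasi-evolutionary-stable-state segmentation across mutation
    rates, Gaussian mutual-information estimators computed across
    simulation ensembles, information-theoretic individuality scores for
    groups of species at multiple scales, transfer entropy and
    whole-minus-sum / revised integrated information between species and
    their environment.  Includes a vector-autoregressive fixture
    generator with closed-form information-theoretic ground truth for
    estimator validation, and a reduced-scale analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    MASS
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
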