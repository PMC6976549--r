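Package: divlik
Title: Likelihoods for Diversity-Dependent and Time-Dependent
    Diversification Models on Reconstructed Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the likelihood of the branching times of an ultrametric
    reconstructed phylogeny under birth-death diversification models whose
    per-species speciation and extinction rates may depend on the standing
    diversity and on time.  The likelihood is obtained by propagating a
    truncated vector of hidden-lineage probabilities (the Q-vector) along the
    branches and through the nodes of the tree, with support for two
    incomplete sampling schemes (a known number of unsampled extant species,
    or an independent sampling probability per species) and conditioning on
    crown survival.  Independent analytical likelihood formulas for the
    diversity-independent and the pure-birth diversity-dependent special
    cases, a generating-function coefficient oracle, the Kendall
    time-dependent birth-death auxiliary functions, a master-equation solver,
    and an exact Gillespie tree simulator are included so that all routes to
    the same likelihood can be cross-checked numerically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
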