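Package: allomacro
Title: Phylogenetic Comparative Analysis of Metabolic Allometry and
    Macroevolutionary Regime Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating allometric scaling relationships across a
    phylogeny while accounting for shared ancestry and within-species
    measurement error, and for characterising the macroevolutionary dynamics
    of the traits involved. Provides phylogenetic generalized least squares
    with Pagel's lambda (linear, curvilinear and grouped variants), an
    iterative measurement-error regression in the spirit of Ives, Midford
    and Garland, phylogenetic signal and repeatability estimation, Mk-model
    fitting with model averaging and stochastic character mapping,
    maximum-likelihood multi-rate Brownian motion and multi-optimum
    Ornstein-Uhlenbeck fits, reversible-jump MCMC detection of shifts in
    trait optima and in allometric slopes, phylogenetic path analysis by
    d-separation with CICc model averaging, and a synthetic-data generator
    that reproduces the statistical structure of an individual-level
    allometry study so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    nlme,
    phytools,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
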