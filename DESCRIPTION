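Package: csfs
Title: Conditioned Site Frequency Spectra and Finite-Sites Mutation Rate Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how mutation-rate variation shapes the human
    site frequency spectrum (SFS). Implements folded and unfolded spectrum
    summaries with hypergeometric subsampling, piecewise-exponential
    demographic models with analytic and simulated expected spectra,
    finite-sites Jukes-Cantor mutation dropping on Kingman coalescent
    genealogies, a mean-preserving lognormal within-mutation-type rate
    mixture with Bayes conditioning on polymorphism, construction of the
    phylogenetically-conditioned SFS (cSFS) from human plus primate site
    tables, a two-category molecular-clock model for mutation-rate
    distributions at parallel-substitution sites, logistic regression of
    rare-variant probability on mutation type and substituted species with
    exact permutation trend tests, and a synthetic site-table generator that
    provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
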