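Package: crc3s
Title: Three-Source Capture-Recapture Population Size Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the size of hidden populations from
    three-source capture-recapture data: construction and validation of
    2^k-1 capture-history contingency tables from per-occasion totals and
    overlaps, a Gibbs sampler for the Bayesian nonparametric latent-class
    capture-recapture model (Dirichlet-process mixture of product-Bernoulli
    capture profiles) with highest-density credible sets, classical
    Lincoln-Petersen/Chapman and independence-MLE comparators,
    respondent-driven-sampling recruitment-homophily and MCMC convergence
    diagnostics, survey sample-size calculators, and a synthetic-data
    generator for capture histories and recruitment chains. Ships the
    published provincial capture tallies of the 2021 Rwanda national MSM
    size-estimation study and an analysis workflow reproducing its national
    and provincial estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
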