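Package: factorialvc
Title: Genetic and Maternal Variance Components from Full Factorial Mating Designs
Version: 0.1.0
Authors@R: person("Avery", "Lindqvist", email = "avery.lindqvist@example.org",
    role = c("aut", "cre"))
Description: Analysis of full factorial (North Carolina II) mating designs
    with mixed-effects models. Converts replicate-level offspring counts to
    individual-level records, estimates dam, sire, and dam-by-sire variance
    components by REML/ML for Gaussian phenotypes and by Laplace
    approximation for binomial and Poisson phenotypes (with latent-scale
    residual variances and an observation-level random effect for
    overdispersion), decomposes phenotypic variance into additive genetic,
    nonadditive genetic, and maternal components, tests components by
    likelihood-ratio and parametric-bootstrap methods, and provides
    bootstrap-t/BCa and delete-d jackknife confidence intervals, pairwise
    group comparison, simulation-based power analysis, and simple bar/box
    visualizations, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
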