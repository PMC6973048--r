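Package: phenosynch
Title: Flowering Phenology Statistics, Synchrony Indices, and Life-Form
    Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of individual-level flowering
    records collected on a weekly census calendar. Computes species-level
    phenological variables (total, mean and variance of flowering length,
    onset variance, moment skewness and kurtosis, Morisita's aggregation
    index), the Loreau-de Mazancourt community-wide synchrony index with
    species-bootstrap confidence intervals, bootstrap
    rarefaction-extrapolation curves with BIC-based model selection for
    sample-size standardization, life-form comparisons via data-driven test
    selection (Student's t, Wilcoxon, Fligner-Policello) with Holm
    correction and gamma/Gaussian mixed models with a genus random
    intercept, and phylogenetic-signal testing (independent contrasts,
    Blomberg's K, tip-shuffling permutation). Includes a synthetic-data
    generator emulating the weekly census protocol, Yule tree simulation
    and Brownian-motion trait evolution, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    car,
    lme4,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
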