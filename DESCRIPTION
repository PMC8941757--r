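Package: codemog
Title: Comparative Demographic Inference from Site Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative phylogeographic demographic inference
    from ddRAD-like SNP data. Implements site frequency spectrum (SFS)
    construction from genotypes with hypergeometric down-projection and
    folding, a single-population Kingman coalescent simulator under
    piecewise-exponential demography, composite-likelihood demographic
    scenario selection with AIC and Akaike weights plus parametric
    bootstrap confidence intervals, and hierarchical approximate Bayesian
    computation over the aggregate SFS to estimate the proportion of
    co-distributed populations sharing a synchronous bottleneck, its
    strength and dispersion. Includes rarefied diversity statistics,
    species-level comparisons, and a synthetic-data generator with known
    demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml, vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
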