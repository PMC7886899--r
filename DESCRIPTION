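Package: relspectrum
Title: Phenotypic Covariance Across the Relatedness Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the phenotypic covariance between pairs of
    individuals changes with their genomic relationship, from nominally
    unrelated pairs through to monozygotic twins. Implements binned and
    individual-level Haseman-Elston regression with blocked-jackknife standard
    errors, an equilibrium model of phenotypic assortative mating that inverts
    bin covariances to the equilibrium heritability and the correlation between
    mates, full-sib identity-by-descent regression (pair-level and restricted
    maximum likelihood variance components), design-expectation adjustments for
    full-sib and twin estimates under assortative mating, and fixed-effect
    inverse-variance meta-analysis. A multi-generation cohort simulator with
    phenotypic assortment, incomplete linkage disequilibrium between causal and
    marker variants, shared environment, additive-by-additive epistasis and
    covariate stratification provides synthetic data with the statistical
    structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
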