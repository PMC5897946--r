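Package: salmospot
Title: Spot Pattern Quantification and Variance-Component QTL Mapping in
    Atlantic Salmon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of skin spot patterns in
    Atlantic salmon and their genetic basis.  Provides standardized
    landmark-based region-of-interest construction and connected-component
    spot detection on flank photographs, size-adjusted spot densities with
    explicit exclusion rules, Clark-Evans average nearest-neighbour
    clustering statistics for point patterns, and a pedigree-based
    variance-component QTL scan: numerator relationship matrices,
    nuclear-family haplotype phasing, position-wise identity-by-descent
    matrices, REML mixed models with arbitrary covariance structures,
    likelihood-ratio genome scans and permutation-based genome-wide
    significance thresholds.  A synthetic-data module simulates point
    patterns, rendered spot images and multi-strain half-sib cohorts with
    known ground truth so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    lme4,
    EBImage,
    png,
    jsonlite,
    yaml,
    tibble,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
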