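Package: mdrscan
Title: Mixture Density Regression for Genome-Wide Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the genomic determinants of recent positive selection with
    a two-component Gaussian mixture density regression: the per-gene-window
    probability of a selection-enriched component is a sigmoid-linked linear
    function of standardized genomic covariates, fitted by maximum likelihood
    (L-BFGS-B) with chi-square likelihood-ratio tests per covariate. Includes
    the preprocessing pipeline that builds the model inputs from integrated
    haplotype score (iHS) scans: allele-frequency-bin standardization of raw
    iHS, gene-centered fixed-size windows, window mean absolute iHS,
    genetic-map interpolation of recombination rates, interval densities with
    assembly-gap exclusion, GC content, and gene-level covariates; plus a
    synthetic-data generator (model-true datasets and a toy genome) that makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
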