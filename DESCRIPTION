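Package: clonetrace
Title: Subclone Reconstruction and Clonal Replacement Analysis for Multi-Region Tumor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tumor subclonal architecture from multi-region
    allele-specific copy-number segments, sequencing variants and single-cell
    copy-number profiles. Estimates mutated sample and clone fractions from
    log-ratio, mirrored B-allele frequency and variant allele frequency;
    clusters events into subclones under pigeonhole and nesting constraints;
    builds rooted maximum-parsimony clone phylogenies; computes genomic
    diversity (IGD), irregularity and proportion-of-progeny statistics;
    classifies collateral clonal replacement versus linear evolution under
    treatment; and approximates two-dimensional subclone territories. A
    synthetic-tumor generator with known ground truth makes every pipeline
    stage testable end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
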