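Package: denovoscan
Title: Identification and Characterization of De Novo Gene Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A synteny- and homology-based pipeline for identifying de novo
    protein-coding gene candidates in a focal genome and characterizing their
    protein foldability, structural-ensemble convergence, expression
    specificity and sequence features. Includes a random-expectation
    calibration of spliced-alignment scores via a two-phase exponential decay
    model, origination-branch inference from per-branch syntenic evidence,
    pLDDT-based foldability classification, TM-score ensemble metrics with
    density-peaks conformation clustering, tissue and sex specificity
    statistics (tau, normalized z-scores), testis stage-profile clustering,
    and a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ape,
    jsonlite,
    minpack.lm,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
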