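Package: vintegrate
Title: Detection of Viral Integration Sites from Paired-End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects virus integration sites in a host genome from paired-end
    sequencing reads. Candidate chimeric read pairs are screened by a
    mismatch-tolerant k-mer filter against a virus database, confirmed by a
    sensitive seed-and-extend local aligner with expect-value ranking,
    clustered by host position with an insert-size-aware threshold,
    refined (complex-read and duplicate filters, split-read rescue by
    targeted Smith-Waterman) and turned into breakpoint calls with strand
    voting, split-read medians and consensus-assembly fallback. Includes a
    seeded infected-genome and read-pair simulator plus evaluation and
    operating-curve utilities for benchmarking sensitivity, false-positive
    fraction, downsampling robustness and breakpoint accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    generics,
    ggplot2,
    methods,
    Biostrings,
    S4Vectors,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
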