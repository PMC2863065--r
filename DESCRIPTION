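Package: isoformlm
Title: Isoform Abundance Estimation from RNA-Seq Read Compatibility Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the relative abundances of known splice isoforms from
    RNA-Seq read counts partitioned into isoform-compatibility subsets, using
    a linear model whose design matrix is computed from empirical (generally
    non-uniform) read start-position and read-length distributions. Provides
    feasible weighted least squares estimation of transcript sampling
    probabilities with conversion to molar isoform proportions and empirical
    bootstrap confidence intervals, a read simulator for recovery and
    coverage studies, chi-square tests for differential splicing and
    two-proportion z-tests for differential gene expression with
    Benjamini-Hochberg control, multiread handling via k-mer indexed design
    matrix masking, and a k-mer sharing gene graph partitioned into connected
    components that define joint-estimation groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    stats,
    stringi,
    tools,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
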