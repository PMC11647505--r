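Package: trflow
Title: Small RNA Fragment Classification and Differential Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained small RNA-seq analysis workflow for tRNA-derived
    fragments (tRFs) and rRNA-derived small RNAs (rsRNAs). Builds mature tRNA
    alignment references (intron splicing, 3' CCA addition, His G-1), trims
    adapter/UMI read structure, resolves multi-mapping reads to a single
    primary category with tRNA-first precedence, types tRNA reads by fragment
    position (whole, tRF_5', tRF_3', tRF_other) and specificity tier, counts
    features, and calls differential abundance between conditions with a
    moderated negative-binomial Wald procedure. Includes a synthetic read
    generator with per-read ground truth so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
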