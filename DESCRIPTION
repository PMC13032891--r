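Package: triodisomy
Title: Trio-Based Detection of Uniparental Disomy with a Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects uniparental disomy (UPD) events from jointly genotyped
    parent-offspring trios. A five-state hidden Markov model over the 27
    father-mother-proband genotype combinations distinguishes Mendelian
    inheritance from paternal/maternal iso- and heterodisomy, decodes
    per-chromosome inheritance with the Viterbi algorithm, and aggregates
    contiguous non-Mendelian states into coordinate-resolved events annotated
    with Mendelian-error counts, likelihood-ratio statistics and per-sample
    depth ratios. Includes post-processing (event collapsing, recurrent-region
    detection and flagging, depth-based CNV exclusion), a Hardy-Weinberg trio
    simulator with implanted UPD events, and a benchmark harness measuring
    sensitivity, false positives and coordinate accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
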