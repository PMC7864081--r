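Package: pathcoact
Title: Pathway Coactivation Analysis with Single-Sample GSEA and Bootstrap Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores per-sample pathway activity in bulk RNA-seq cohorts with the
    single-sample gene set enrichment analysis (ssGSEA) rank statistic, and tests
    whether two pathways are transcriptionally coactivated by correlating their
    activity scores across samples and comparing the observed Pearson coefficient
    with a bootstrap null distribution of random size-matched gene signatures.
    Ships the 8-gene G12/13 signaling signature and a 24-gene YAP/TAZ target
    signature, GMT input/output, median-of-ratios count normalization, and a
    negative-binomial cohort simulator with two planted gene modules whose latent
    activities have a configurable correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    withr,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
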