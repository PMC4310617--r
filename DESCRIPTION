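Package: promarch
Title: Promoter Architecture and Expression Breadth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links the transcription-factor binding-site (Tfbs) architecture
    of proximal promoters to the breadth of gene expression. Provides
    BED-based peak-to-promoter mapping, per-transcript Tfbs-count metrics,
    expression breadth (BoE) and preferential-expression (PEM) summaries from
    TPM tables, an effective-promoter-size estimator, a within-promoter peak
    "stacking" randomization test, promoter-shuffle permutation nulls,
    Spearman partial correlations, correlation-distance clustering, a
    support-vector-machine breadth predictor with scrambled/retained
    controls, Jaccard-index promoter divergence between paralogs with
    duplication-age stratification, and seeded synthetic-data generators
    with planted, recoverable effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    pROC,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
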