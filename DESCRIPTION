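Package: pancontext
Title: Pan-Cancer Query-Gene Association Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for charting the pan-cancer association
    landscape of a single query gene across tumor cohorts and cell-line
    panels: per-cancer-type Spearman co-expression screening, pre-ranked
    geneset enrichment with permutation-normalised scores, mutation-status
    stratified delta-correlation and delta-enrichment analyses, Cox
    proportional-hazards survival screening of the median-dichotomized query
    gene, second-order correlation-versus-hazard analyses, consensus K-means
    clustering of cancer types by correlation profile, and drug-response
    correlation screens with eligibility gating. Includes a synthetic cohort
    and cell-line generator with planted rank correlations (Gaussian copula),
    proportional-hazards survival and monotone drug-response links, so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
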