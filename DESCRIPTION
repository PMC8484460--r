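Package: immunoclass
Title: Immune Molecular Classification of Tumors by NMF Virtual
    Microdissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers immune-related molecular classes in bulk tumor
    expression cohorts by non-negative matrix factorization (NMF) virtual
    microdissection. Provides KL-divergence multiplicative-update NMF with
    multi-run consensus clustering, single-sample gene-set enrichment
    (ssGSEA) scoring, immune-factor selection, exemplar-gene extraction,
    random-forest/MDS label refinement, nearest template prediction (NTP)
    for splitting the immune class into immune-activated and
    immune-suppressed subclasses, a 150-gene transfer classifier for
    validation cohorts, subclass mapping against immunotherapy responder
    profiles, Kaplan-Meier/log-rank and contingency statistics, and a
    synthetic cohort generator with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
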