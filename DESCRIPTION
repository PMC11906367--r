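Package: chancestry
Title: Clonal Hematopoiesis, Genetic Ancestry and Germline Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying clonal hematopoiesis (CH) across admixed and
    European cohorts: rule-based CH driver calling from somatic variant
    records, local-ancestry aggregation and ancestry-CH association models,
    Firth penalized logistic regression with variant QC, linkage
    disequilibrium statistics, conditional scans and genomic-inflation
    diagnostics, rare-variant gene-level collapsing under qualifying-variant
    models with Cochran-Mantel-Haenszel cross-cohort meta-analysis,
    inverse-variance and sample-size-weighted meta-analysis with Cochran's Q
    heterogeneity, and telomere-length polygenic score construction and
    validation. A synthetic-cohort generator emulating three-way admixture,
    ancestry-dependent smoking and CH risk, ancestry-specific allele
    frequencies and a heritable telomere trait makes the whole pipeline
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
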