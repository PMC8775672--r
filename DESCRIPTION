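Package: comorbnet
Title: Phenotypic Disease Network Analysis of Comorbidity from Hospital
    Discharge Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comorbidity analysis of an index condition (by default
    ischemic heart disease, ICD-10 I20-I25) from long-format hospital
    discharge records: ICD-10 three-character phenotype aggregation with
    chapter and chronicity filters, matched case-control cohort construction,
    per-condition prevalence and odds-ratio statistics with Bonferroni
    correction and an enrichment screen, observed-to-expected-ratio (OER)
    phenotypic disease networks with significance gating at the 99 percent
    confidence level, network metrics, fast-unfolding (Louvain) community
    detection, sex- and age-stratified network comparison, and a calibrated
    synthetic discharge-record generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
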