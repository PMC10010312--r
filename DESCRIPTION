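Package: immunocentroid
Title: Immunogenomic Profiling of Immunotherapy Response in Renal Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pretreatment tumor immunogenomic analysis of
    immunotherapy response in bulk RNA-seq cohorts: expression filtering and
    upper-quartile/median normalization, mean-expression immune gene-set
    signature scoring with group-difference statistics and hypergeometric
    overrepresentation analysis, a cross-validated nearest-centroid response
    classifier with in-fold supervised gene selection, a centroid-based
    molecular subtype classifier, clinical endpoint statistics (response
    rates, Kaplan-Meier, Cox proportional hazards, log-rank, Fisher exact,
    Kruskal-Wallis, multivariable logistic regression), and a
    negative-binomial synthetic cohort simulator with planted immune
    programs and right-censored survival for end-to-end validation.
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
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
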