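Package: gatrb
Title: T-Cell Receptor Beta Repertoire Mining for Glatiramer Acetate Response Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining bulk T-cell receptor beta (TRB) repertoires for
    treatment-associated public clonotypes and carrying the result through to a
    clinical treatment-by-HLA interaction analysis. Implements case/control
    Enhanced-Sequence discovery with one-sided Fisher exact tests, one-wildcard
    public motif expansion and multi-cohort replication; HLA carrier imputation
    from repertoire features with a two-covariate logistic model; clonal
    breadth/depth biomarker scoring and treatment-exposure prediction by ROC
    analysis; carrier-level linkage disequilibrium, exact matching, and linear,
    Cox and Andersen-Gill interaction models for clinical outcomes. Includes a
    synthetic multi-cohort repertoire and outcome generator emulating the data
    structure these analyses assume, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    pROC,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
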