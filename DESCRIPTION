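Package: targetadr
Title: Target-Adverse Drug Reaction Association Mining from Secondary
    Pharmacology Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline linking in vitro secondary pharmacology
    panel results to clinical adverse drug reactions (ADRs). Summarizes
    replicate qualified AC50 results, merges concordant assay protocols
    into assay groups, computes free-Cmax safety margins, constructs
    MedDRA-hierarchy-aware ADR training sets from label-mined and
    pharmacovigilance annotations, tests assay-ADR associations with the
    Kruskal-Wallis test and ROC AUC, de-confounds correlated off-target
    activities with one-standard-error lasso models, and flags unpublished
    off-target activities that may explain known drug ADRs. Includes a
    synthetic-data generator with a planted causal target-ADR map for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
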