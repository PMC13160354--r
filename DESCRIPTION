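Package: panscreen
Title: Pan-Cancer Single-Gene Expression Biomarker Discovery from Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of pan-cancer single-gene expression biomarkers of drug
    sensitivity from cell-line screening data. Implements tissue-of-origin
    correction of expression matrices (within-tissue z-scoring and
    residualization on lineage labels), per-drug penalized regression under
    repeated cross-validation with tissue-weighted Pearson evaluation,
    shuffled-response null models for informative-model selection, coefficient
    rank aggregation with pathway-level recurrence and stability statistics,
    preranked drug-set enrichment with permutation p-values, and cancer-type
    context mapping. Includes a synthetic-screen generator with planted
    biomarkers and lineage-proxy decoys for end-to-end validation, and a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
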