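Package: ppindex
Title: Pyroptosis Potential Index and Pan-Cancer Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a directional single-sample gene-set enrichment score,
    the pyroptosis potential index (PPI), from a curated catalog of positive
    and negative pyroptosis regulator genes, and runs the downstream
    pan-cancer analysis battery around it: tumor/normal differential PPI,
    survival stratification by log-rank tests and univariate Cox regression,
    permutation GSEA with normalized enrichment scores and FDR, association
    of the index with immune microenvironment and molecular features, tumor
    mutation burden from mutation tables, and expression-based drug
    sensitivity comparison via a cross-validated ridge model. A seeded
    synthetic cohort generator emulates the shapes and statistical structure
    of the pan-cancer inputs so every stage runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
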