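Package: campnets
Title: Membrane Protein Interaction Prediction and Cancer Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-protein interactions of integral membrane
    proteins from interolog templates using a six-component integrated
    similarity score (interacting-region similarity, template quality,
    joint sequence similarity, similarity rank, evolutionary conservation,
    and network topology), and links the resulting membrane-protein
    partner communities to pathways across cancers via co-expression
    enrichment with permutation nulls, Stouffer meta-analysis, combined
    prognostic scores with survival stratification, and co-IP/FRET assay
    metrics. Ships a seeded synthetic-data generator so the full pipeline
    runs on planted-structure fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
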