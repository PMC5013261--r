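Package: explinkr
Title: Exposure-Disease Linkage Prediction from Pathway Enrichment of
    Transcriptomic Measures
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-step pipeline for predicting linkages between an
    environmental exposure and classes of human disease from per-gene
    expression measures. Pathways are represented as gene-labeled graphs
    (read from KGML or plain tables) and scored for coordinated expression
    change with a topology-weighted rank statistic under a permutation
    null; gene-disease association tables are scored the same way; and the
    overlap between the significant-pathway sets of an exposure dataset
    and a disease class is assessed with an exact hypergeometric test.
    Includes a synthetic-data generator with planted signal so every stage
    of the pipeline can be exercised and calibrated without any external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
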