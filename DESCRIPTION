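Package: ureascape
Title: Chemical-Space and Activity-Landscape Analysis of Urease Inhibition Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curates heterogeneous enzyme-inhibition bioassay tables
    (IC50/Ki normalization against assay controls, structure
    standardization, InChIKey deduplication) and profiles the resulting
    compound set: Morgan fingerprint similarity, hierarchical clustering
    with data-driven maximum-common-substructure scaffolds, t-SNE
    chemical-space maps, physicochemical and structural-alert filtering
    (rule-of-5, PAINS/Brenk-style catalogs), activity-cliff landscape
    analysis with safe-bet/dead-end profiling, and interpretable
    IF-THEN activity rules extracted from a depth-capped decision tree.
    Includes a synthetic bioassay-library generator with planted ground
    truth (scaffold families, activity cliffs, descriptor rules) so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    rpart,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
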