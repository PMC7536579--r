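Package: hnf1astrat
Title: Multi-Dimensional Functional Stratification of HNF1A Missense Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies HNF1A missense variants along the benign / type 2
    diabetes risk / MODY continuum from multi-assay functional data.
    Provides a synthetic two-laboratory assay-panel generator, readers and
    writers for long-format functional tables with HGVS protein-name
    parsing, dataset polishing (replicate aggregation, EMSA exclusion,
    isoform and domain position scores, standardization), principal
    component decomposition with variable contributions, k-means and Ward
    hierarchical clustering with a validity-index vote for the number of
    clusters, dendrogram tanglegram entanglement with greedy untangling,
    reference-variant zone annotation, and an auditable allele-frequency
    aware reclassification rule engine with registry-level impact
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    cluster,
    mclust,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
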