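Package: spotnet
Title: Amyloid Hotspots and Consensus Co-Expression Meta-Modules for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Visium-style spatial transcriptomics of
    amyloid pathology. Integrates segmented amyloid objects ("binaries") with
    spot transcriptomes, computes Getis-Ord Gi* hotspot fields, and calls
    amyloid-associated genes with a quasi-Poisson GLM, Benjamini-Hochberg FDR
    and a positive-correlation filter. Builds region-wise weighted
    co-expression networks from pseudobulk log2-CPM profiles (soft-power
    selection, topological overlap, module detection, module eigengenes and
    kME), merges modules across cortical regions into meta-modules via a
    combined Jaccard/eigengene-correlation dissimilarity, and tests modules
    for differential eigengene expression. Also provides consensus
    cell-to-region annotation from multi-sample spatial mappings, attribution
    of spatial differentially expressed genes to cell populations via marker
    tables, and a synthetic-data generator with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    MASS,
    withr
Config/testthat/edition: 3
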