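Package: glandst
Title: Spatial Transcriptomics Portrayal of Holocrine Gland Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for Visium-style spatial transcriptomics of
    holocrine glands (meibomian and sebaceous). Provides a synthetic
    gland-section generator with planted maturation structure, spot QC and
    normalization, PCA/UMAP embedding, shared-nearest-neighbor modularity
    clustering, Wilcoxon marker detection, self-organizing-map transcriptome
    portrayal with overexpression-module detection and difference portraits,
    principal-graph pseudotime with windowed gene-set dynamics, cross-gland
    stage comparison (Venn, Sankey, volcano inputs, joint embedding), and
    local hypergeometric overrepresentation analysis with tissue coloring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    uwot,
    RANN,
    matrixStats,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
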