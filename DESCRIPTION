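Package: batmodules
Title: Gene Expression Module Discovery in Clonal Brown Adipocyte
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts gene expression modules from paired clonal bulk
    RNA-seq of brown preadipocytes and differentiated adipocytes.  Genes
    are embedded with a Laplacian eigenmap built on a Mahalanobis-distance
    k-nearest-neighbour graph, uninformative genes near the geometric
    median of the embedding are removed by an exact one-dimensional
    2-means split, the remaining genes are assigned to modules by
    silhouette-guided k-means, and modules are screened by gene-wise
    correlation to per-sample BATness scores, a paired
    pre-/differentiated expression-stability screen, and hypergeometric
    gene-set over-representation.  A negative-binomial clonal-expression
    simulator with planted modules, planted stable genes and planted
    BATness scores provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Matrix,
    ape,
    fgsea,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
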