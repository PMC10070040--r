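Package: scMultiClust
Title: Fusion of Paired Single-Cell Multi-Omics Data and Mining of
    Multiple Diverse Clusterings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint modelling of paired single-cell RNA-seq counts and
    single-cell ATAC accessibility profiles. An attention-augmented
    autoencoder with an omics-label discriminator extracts omics-specific
    (individual) signal, a contrastive mutual-information objective
    extracts cross-omics shared (common) signal, and zero-inflated
    negative binomial and Bernoulli generative decoders regularize the
    fused co-embedding and impute dropout events. A second stage projects
    the co-embedding into several attention-head subspaces, penalizes
    redundancy between heads with a Hilbert-Schmidt independence
    criterion, and sharpens each subspace clustering with a
    Kullback-Leibler target-distribution loss, yielding multiple diverse,
    high-quality cell partitions (for example cell types and cell
    states). Includes a paired multi-omics simulator with planted
    orthogonal partitions, clustering-evaluation metrics, Matrix Market
    and delimited-text readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
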