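Package: TransgeneOverlay
Title: Projection-Target Assignment from Retrograde Viral Transgene
    Barcodes in Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats the mRNAs of retrogradely delivered viral transgenes
    (recombinases, fluorophores) as connectivity barcodes inside
    single-cell and single-nucleus RNA-seq data. Provides
    transgene-augmented reference construction (FASTA/GTF) for external
    aligners, barcode discriminability checks, per-cell quality control
    and normalization including TF-IDF gene weighting, PCA/kNN/Leiden
    clustering support restricted to endogenous genes, Mann-Whitney
    marker ranking with Benjamini-Hochberg correction, Jaccard-based
    cluster merging, transgene overlay with hypergeometric
    projection-identity assignment, an ambient-RNA contamination
    diagnostic based on the neuronal versus non-neuronal compartment
    split, ground-state perturbation checks, and 2x2 contingency
    statistics for FISH-style co-expression validation. A bundled
    negative-binomial droplet simulator with ground-truth labels makes
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
biocViews: SingleCell, Transcriptomics, Clustering, QualityControl,
    Normalization, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
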