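Package: spatlink
Title: Cross-Modal Alignment, Annotation and Decomposition for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools that link spatial transcriptomics and histology through a shared
    embedding space. Expression profiles are converted to ranked gene sentences and
    embedded alongside image features by a deterministic dual reference encoder with a
    symmetric contrastive objective and linear adapter fine-tuning. On top of the
    embeddings the package provides embedding-augmented nonrigid coherent point drift
    registration of adjacent tissue sections with a rigid projection, zero-shot tissue
    annotation from bulk profiles or marker genes with dual-model score fusion,
    cell-type decomposition via a probabilistic mapping matrix optimized over cosine
    distances with non-maximum-suppression refinement, image-to-transcriptomics
    retrieval scored by quantile recall, similarity-weighted spatial gene expression
    prediction with cross-validation, the matching evaluation-metric suite, and seeded
    synthetic-data generators for paired cohorts, perturbed sections, depth
    downsampling and pseudo-spot binning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
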