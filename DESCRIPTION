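Package: spotCTA
Title: Computational Tissue Annotation for H&E Images Paired with Visium
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell tumor/immune/stroma annotation of hematoxylin and
    eosin (H&E) images and its integration with Visium spatial
    transcriptomics. Provides Beer-Lambert stain modelling and automated
    stain-vector estimation, watershed nucleus segmentation, cell expansion
    and morphology/optical-density feature extraction, a mean/variance
    normalized random-forest cell classifier, cell-to-spot alignment with
    per-spot composition, spot quality-control filters, deconvolution-method
    benchmarking (Spearman correlation, Kruskal-Wallis with Dunn's post hoc
    test and Benjamini-Hochberg correction), purity-guided copy-number clone
    calling by genomically smoothed relative expression and Ward clustering,
    and downstream spot reports. A synthetic-data module generates H&E-like
    scenes, hexagonal spot lattices, noisy deconvolution fractions and
    clone-structured count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
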