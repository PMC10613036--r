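Package: seedct
Title: Micro-CT Phenotyping of Seed Morphological Structure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for X-ray micro-CT phenotyping of cotton seeds. Reads
    grayscale slice stacks into voxel volumes, segments individual seeds by
    Otsu thresholding, 3D hole filling and marker-based watershed, splits each
    seed into kernel, coat and cavity components by per-seed histogram
    analysis, reconstructs isosurfaces and measures 11 morphological traits
    (linear dimensions, volumes, surface areas, average coat thickness, seed
    fullness) plus three derived evaluation indices (coat specific surface
    area, coat thickness ratio, seed density ratio). Includes a synthetic
    seed-phantom generator with exact ground truth for end-to-end validation,
    an optional trainable voxel-classifier segmentation path with patch-based
    sliding-window inference, and the statistical workflow used for phenotype
    populations (descriptive statistics, Pearson correlation, z-scoring, Ward
    clustering, LSD/Bonferroni group comparison, trend fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    png,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
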