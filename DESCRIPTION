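Package: HistoDMRI
Title: Comparing Gray-Matter Cytoarchitecture with In-Vivo Diffusion MRI Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison between gray-matter cytoarchitecture,
    measured as cell area density and its spatial heterogeneity on
    Nissl-stained histology sections, and in-vivo diffusion MRI
    microstructure measures: fractional anisotropy and trace from the
    diffusion tensor model, and mean squared displacement and
    return-to-origin probability from a biexponential (two-tensor plus
    free-water) signal model. Provides the tensor and biexponential model
    fits, a morphological cell-segmentation pipeline with Dice-based
    quality control, regional average and heterogeneity statistics
    (including an inter-voxel mean absolute pairwise difference statistic
    and a grid-resampled cell-area-density variance), a Pearson/FDR
    correlation stage split by cortical and subcortical region class, and
    a synthetic-data generator that emulates the full study design with a
    tunable coupling between local cell density and local diffusivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    EBImage,
    minpack.lm,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
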