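Package: atriaseg
Title: Left and Right Atrium Segmentation of Cardiac MRI with a Nested
    Residual U-Network and Classical Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Segments the left and right atria in short-axis cardiac MRI
    slices. Implements a nested residual U-network ("UU-NET") whose
    encoder and decoder stages are themselves small U-shaped modules
    linked by concatenation and addition, a deconvolution-network
    baseline, and four classical baselines (seeded region growing, Otsu,
    iterative and maximum-entropy thresholding), trained with a soft Dice
    loss whose analytic gradient is exposed. Includes Dice and Hausdorff
    evaluation metrics, max-normalization and augmentation preprocessing,
    PNG/NIfTI raster input and output, and a synthetic short-axis phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
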