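Package: rectseg
Title: Region-Specific U-Net Segmentation of Rectal Structures on T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating region-specific deep-learning
    segmentation models for rectal anatomy (outer rectal wall, lumen,
    perirectal fat) on T2-weighted MRI slices. Provides a seeded synthetic
    rectal-phantom generator with ground-truth labels, an MRI harmonization
    chain (resampling, bias-field correction, reference-muscle intensity
    normalization, center-crop/resize), 2D U-Net models with either a
    single-region sigmoid head or a multiclass softmax head together with
    Dice-loss training and on-the-fly augmentation, validation-optimized
    binarization with largest-connected-component post-processing, contour
    agreement metrics (Dice, Hausdorff and discrete Frechet distances on a
    pseudo-volumetric basis), and Wilcoxon rank-sum reporting with Bonferroni
    correction. The neural-network layers are implemented natively on
    RcppArmadillo so the whole pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
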