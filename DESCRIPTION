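Package: mdcseg
Title: Two-Step Semi-Supervised Volumetric Segmentation with
    Multi-Dimensional Consistency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a two-step semi-supervised pipeline for binary
    segmentation of tubular structures (e.g. intestine) in 3D grayscale
    volumes with scarce voxel-level annotation. Step one trains a 2D
    U-shaped network with windowed self-attention on axial slices from
    the labeled volumes; its argmax predictions, merged slice-wise over
    sliding-window patches, become frozen pseudo-labels for the unlabeled
    volumes. Step two trains a 3D convolutional U-Net on labeled patches
    with a weighted cross-entropy plus soft-Dice loss and on unlabeled
    patches with a Dice-only consistency loss against the pseudo-labels.
    Includes NIfTI volume IO with isotropic resampling, a synthetic
    tubular-phantom cohort generator, overlap-averaged patch stitching,
    sparse-slice evaluation metrics, multi-seed aggregation and the
    Wilcoxon signed-rank test. Networks are scale-configurable and the
    tiny presets train on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
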