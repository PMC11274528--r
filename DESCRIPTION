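Package: lggrowth
Title: Quantifying Diffuse Low-Grade Glioma Growth from Longitudinal
    Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the growth of diffuse low-grade gliomas
    (LGG) from longitudinal 3D lesion segmentation masks. Implements
    optimized 1D/2D/3D linear tumor measurements (tumor width, perpendicular
    width, and the three axis-aligned diameters) with post-surgical
    measurement rules (largest-residue selection, resection-cavity
    avoidance), segmented volume, the mean tumor diameter (MTD) in both its
    diameter-based and volume-based variants, the velocity of diameter
    expansion (VDE), RANO-derived and LGG-optimized progression
    classification, and the associated agreement statistics (Pearson
    correlation, Lin's concordance, Bland-Altman limits of agreement,
    cross-tabulation diagnostics, and ROC-optimal threshold derivation).
    A synthetic lesion-cohort generator produces post-surgical LGG-like
    geometry (irregular residues, resection cavities, satellites,
    anisotropic growth at a controlled true VDE) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
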