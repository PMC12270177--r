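Package: ihcseg
Title: Immunohistochemistry-Guided Epithelium Segmentation for Breast TMA Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline that turns paired HE and cytokeratin (CK AE1/AE3)
    restained tissue-microarray (TMA) slide images plus pathologist region
    annotations into four-class pixel ground truths (background, invasive,
    benign and in-situ epithelium), trains an attention-gated U-Net on
    balanced patches, and evaluates segmentations per TMA core. Includes
    H-DAB colour deconvolution and DAB-threshold mask cleaning, automatic
    TMA core detection and HE/CK core pairing, phase cross-correlation
    registration of restained sections, overlap tiling with balanced patch
    sampling and augmentation, tiled inference with probability stitching,
    per-core Dice/precision/recall with zero-denominator conventions and
    subgroup summaries, and a synthetic slide-pair generator so every stage
    is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
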