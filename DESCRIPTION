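Package: dermafuse
Title: Hybrid Handcrafted and Deep Feature Pipeline for Skin Lesion Malignancy Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a hybrid skin-lesion classification
    pipeline. Extracts the dermoscopic ABCD handcrafted features -- shape
    asymmetry, a serrated-contour border-irregularity score, the six-color
    rule, diameter, gray-level co-occurrence texture -- plus the patient's
    Fitzpatrick skin type derived from the individual typology angle (ITA)
    in CIELab. Deep features come from a dual-stream residual squeeze-excite
    convolutional network. Feature selection combines mutual-information
    biased self-attention (SAMI) ranking on handcrafted features with a
    relevance-score optimized selection (OFS) on the fused feature table,
    followed by a multilayer-perceptron classifier. Ships synthetic lesion
    and feature-table generators with known ground truth so the whole
    pipeline is testable without external image datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    withr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
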