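Package: tmaseg
Title: Superpixel-Based Tumor Segmentation of TMA Histopathology Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-assisted segmentation of tissue-microarray (TMA) core
    images into tumor, non-tumor and background regions. Images are
    partitioned into SLIC superpixels, each superpixel is described by 69
    texture features (17 first-order histogram statistics and 6 Tamura
    features per RGB channel), and supervised classifiers assign a tissue
    class to every superpixel, which are then reassembled into a segmented
    image. Includes image enhancement (contrast normalization, histogram
    equalization, histogram matching), ImageJ polygon ROI ingestion,
    majority-vote ground-truth construction, image-level cross-validation
    with per-class precision/recall/F1 metrics, and a synthetic TMA
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    ranger,
    e1071,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
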