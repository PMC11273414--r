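Package: dafh
Title: Deep Attention Fusion Hashing for Content-Based Medical Image Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns compact binary hash codes for labeled medical images with an
    attention-augmented convolutional network trained end to end under a joint
    focal-classification and triplet-metric objective. An intermediate backbone
    feature map is refined by convolutional block attention (channel then
    spatial), fused with the final backbone features, and quantized by a
    learnable steepened hyperbolic tangent so codes are near-binary yet
    differentiable. Includes the full surrounding pipeline: DICOM/PNG ingestion
    with interquartile-range outlier cleaning, augmentation and stratified
    database/query splitting, a synthetic class-structured image generator for
    dependency-free testing, a Hamming-distance retrieval index with popcount
    ranking, mean-average-precision evaluation (MAP, MAP at k, MAP at 1
    confusion matrix), and a command-line interface covering simulate,
    preprocess, train, index, query and evaluate steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
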