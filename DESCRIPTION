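Package: pfseg
Title: Plantar Foot Segmentation for Cold-Stressed Active Infrared Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting plantar feet in single-channel radiometric
    thermal image sequences acquired during recovery from cold stress.
    Implements two-point black-body radiometric calibration and fixed
    temperature windowing, a two-stage adaptive gamma contrast transform
    driven by per-image cumulative-distribution statistics, the PFSNet
    encoder-decoder segmentation network (residual U-blocks, nested dense
    skip connections, convolutional block attention, multi-side-output
    fusion) with a deep-supervision binary cross-entropy loss and a small
    built-in training engine, segmentation and image-quality metrics
    (Dice, IoU, Hausdorff distance, entropy, MSE, PSNR), and a seeded
    synthetic thermogram phantom generator that emulates the cold-recovery
    acquisition protocol for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
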