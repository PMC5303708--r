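Package: canopywtc
Title: Overhead-Image Canopy Segmentation and Waterlogging-Tolerance Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive field phenotyping of individual plants from
    overhead RGB photographs. Segments each frame into soil, green leaf and
    dead (chlorotic or senescent) leaf pixels by color-threshold background
    removal, decorrelation or percentile color stretching, seeded k-means
    clustering and prototype-based class assignment; converts pixel counts
    to projected green and dead areas via a user-supplied mm-per-pixel
    calibration. Computes the waterlogging tolerance coefficient (WTC) and
    its image-based analogue from projected green areas, NDVI, genotype
    means with coefficients of variation, Pearson correlation matrices with
    significance stars, and Fisher's protected LSD letter groupings. Ships
    a seeded synthetic-canopy and trait-cohort generator with pixel-exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jpeg,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
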