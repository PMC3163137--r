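Package: lvdquant
Title: Whole-Slide Quantification of Immunostained Lymphatic Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of immunostained lymphatic vessels on
    whole-slide or tile images of tumor tissue sections. Segments red-stained
    vessel walls by excess-red transformation and Kapur maximum-entropy
    thresholding, rescues vessel lumens by background-referenced brightness
    with wall-adjacency filtering, detects the counterstained tissue
    footprint by Tsai moment-preserving thresholding of the decimated blue
    channel, and computes lymphatic vessel density (vessels per square
    millimetre of stroma) for the whole section and for a peritumoral band
    defined by the Euclidean distance transform of a tumor mask. Spatial
    statistics describe the vessel-to-tumor distance distribution and the
    directional (polar) distribution of vessels around the tumor mass
    centre. A ground-truthed synthetic slide generator supports end-to-end
    validation without real slides.
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
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
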