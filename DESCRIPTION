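Package: stomapore
Title: Segmentation and Measurement of Stomatal Pores in Microscope Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation and morphometry of single plant stomata
    in light-microscope images. A region-based Chan-Vese level-set contour,
    seeded at the centre of the region of interest, extracts the pore without
    prior knowledge of its size or shape; solidity-based shape analysis with
    morphological erosion/dilation disconnects the pore from touching
    structures; the pore boundary is extracted at sub-pixel resolution and
    fitted with a direct least-squares ellipse, from which the major and minor
    axes, area, eccentricity and opening degree are reported in pixels and
    micrometres. Includes a seeded synthetic stoma-image generator with exact
    ground truth for dark-field and bright-field appearance, batch processing
    over image directories with bounding-box sidecars, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
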