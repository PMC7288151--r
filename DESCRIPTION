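Package: lsmtopo
Title: Surface Topography from Light-Sheet Laser Triangulation Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts stacks of light-sheet microscopy images into calibrated
    three-dimensional surface heightmaps by laser triangulation. A bright,
    roughly vertical laser stripe is imaged on a camera; local surface height
    shifts the stripe laterally, so the per-row brightest-column contour of
    each frame encodes a height profile. The package provides the
    triangulation geometry (oblique and orthogonal configurations),
    speckle-robust contour extraction with guided-filter smoothing,
    polynomial pixel-offset calibration with monotone inversion, point-cloud
    and gridded-surface reconstruction with step-height and groove-depth
    metrology, circle-fit curvature estimation, and a synthetic light-sheet
    scene renderer so the whole pipeline can be exercised and validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    interp,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
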