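Package: swfringe
Title: Standing-Wave Fluorescence Fringe Analysis and Membrane Surface
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward optical model and measurement chain for standing-wave
    fluorescence microscopy above a plane mirror. Models sin-squared
    excitation standing waves, emission self-interference and the moire
    beat between them; renders synthetic fringe images of spherical-cap
    calibration specimens and biconcave red-blood-cell membrane shells;
    and recovers axial antinode spacings, moire beat periods and 3D
    surface reconstructions from 2D concentric fringe patterns via
    radial profiling, subpixel peak refinement and contour mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
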