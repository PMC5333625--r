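Package: clpointer
Title: Cathodoluminescence-Pointer Registration for Integrated
    Correlative Light and Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration of fluorescence (FM) and electron (EM) microscope
    image frames in integrated CLEM using cathodoluminescence (CL) pointers:
    electron-beam-generated light spots recorded on the fluorescence camera
    at commanded beam positions. Provides sub-pixel spot localization by the
    radial-symmetry method, sorting of detected spots into pairs with the
    commanded beam grid, closed-form similarity-transform (scale, rotation,
    translation) least squares, estimation and correction of the residual
    distortion field between the two frames, bootstrap estimation of overlay
    accuracy versus pointer count, rendering of registered overlay images,
    and a virtual-microscope simulator that generates FM/EM scenes with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
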