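Package: tomowedge
Title: Subtomogram Averaging, Classification and Difference-Density Mapping
    for Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for the analysis of subtomograms from
    single-axis cryo-electron tomography. Provides MRC/CCP4 volume input and
    output, a synthetic generator of translocon-like phantoms and
    tilt-limited noisy particle datasets with known ground truth,
    missing-wedge-aware constrained cross-correlation, exhaustive rigid
    alignment and wedge-compensated Fourier averaging, focused-mask
    constrained principal component classification of compositional
    heterogeneity, Fourier shell correlation resolution estimation, and
    sigma-thresholded normalized difference-density mapping that localizes
    missing subunits between two density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
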