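Package: spiralmap
Title: Conduction Velocity, Action Potential Duration, and Wavelength
    Analysis for 1D Spiral Cardiomyocyte Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing and analysing micropatterned 1D spiral
    assays of cardiac conduction built from voltage-dye optical recordings.
    Provides the Archimedean spiral micropattern geometry (centerline, arc
    length, raster mask, arc-to-pixel mapping), a seeded kinematic simulator
    that renders action-potential wave propagation as fluorescence image
    stacks, line scans, microelectrode-array recordings, tissue-slice style
    optical maps, and patch-clamp traces with known ground truth, and the
    analysis chain that extracts conduction velocity, APD50/APD80/APD90,
    effective refractory period from S1-S2 pacing, directly measured and
    calculated conduction wavelength, activation maps with longitudinal and
    transverse conduction velocity, and a rule-based classifier of nodal,
    atrial, and ventricular action potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
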