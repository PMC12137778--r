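Package: ulfmt
Title: On-Resonance Magnetization Transfer Imaging Simulation and Analysis
    for Ultra-Low-Field Non-Balanced SSFP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-pool extended-phase-graph (EPG) simulation of non-balanced
    steady-state free precession (SSFP-FID/FISP and SSFP-Echo/PSIF) signals
    with on-resonance bound-pool saturation, digital phantoms emulating
    multi-vial magnetization-transfer (MT) and relaxometry-array experiments
    at ultra-low field (64 mT), and the full magnetization transfer ratio
    (MTR) analysis chain: flip-angle and pulse-width sweeps, symmetry
    analysis, flip-angle-pair selection, MTR maps, ROI statistics,
    histograms, Bland-Altman agreement, and bias-corrected scan-rescan
    coefficients of variation. A brute-force isochromat simulator is
    included as an independent validation oracle for the EPG engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
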