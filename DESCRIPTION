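Package: necroscope
Title: Quantitative Phase Imaging Analysis of Apoptosis and Oncosis
Version: 0.1.0
Authors@R:
    person("Necroscope", "Developers", email = "necroscope@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing apoptotic from oncotic cell death by
    quantitative phase imaging and flow cytometry. Provides a synthetic-data
    generator for off-axis holograms of adherent-cell phase phantoms with
    known dry mass and fate, numerical phase reconstruction (Fourier sideband
    demodulation, quality-guided phase unwrapping, background flattening,
    simulated differential interference contrast), dry-mass quantification and
    segmentation at a fixed phase threshold, time-lapse trajectory
    classification into size-increase, size-decrease and unchanged cells,
    annexin V/propidium iodide quadrant gating with forward-scatter
    back-gating, contingency comparison of morphology against cytometry, and
    rule-based staging of oncosis progression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
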