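Package: trxmap
Title: Difference Maps and Extrapolated Structure Factors for
    Time-Resolved Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pump-probe (time-resolved) crystallographic data
    downstream of merging: weighted Fourier difference electron-density
    maps from dark and photoactivated structure-factor amplitudes,
    extrapolated structure factors with data-driven determination of the
    extrapolation factor by the negative-density-vanishing criterion,
    population-transfer estimation, phased extrapolation from a refined
    model pair, and the geometric observables (torsions, distances,
    ring-plane rotations, helix kinks, hydrogen-bond classes) used to
    describe photointermediate structures.  Includes a synthetic
    two-state crystal simulator with known population transfer so the
    whole pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
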