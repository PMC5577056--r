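Package: fluctedit
Title: Fluctuation Editing of Antibodies from CPMG Relaxation Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies millisecond conformational exchange from CPMG
    relaxation-dispersion data with two-state exchange models (Carver-Richards
    and Luz-Meiboom closed forms, validated against a numerical
    Bloch-McConnell propagator), fits dispersion curves globally over residue
    clusters sharing an exchange rate, and selects non-CDR alanine-mutation
    candidates in antibody variable domains by four criteria (dispersion,
    non-CDR location, residue size, relative solvent accessibility).
    Mutant evaluation tools cover one-site ITC isotherm simulation and
    fitting, binding-thermodynamics decomposition with error-weighted
    heat-capacity regression, DSC enthalpy integration, and distance
    distribution comparison between structural snapshot ensembles. Seeded
    synthetic-data generators make the whole pipeline testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
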