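Package: monosurf
Title: Pulmonary Surfactant Monolayer Biophysics: Iso-Cycle Metrics and
    Monolayer Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of pulmonary-surfactant monolayer
    biophysics. Reads and segments surfactometry traces from
    Langmuir-Blodgett trough (surface pressure vs. area) and constrained
    sessile drop (surface tension vs. area) instruments into
    compression-expansion iso-cycles and computes per-cycle functional
    metrics: extrema (maximum surface pressure / minimum surface tension),
    the compressibility modulus kappa = -A dPi/dA with Savitzky-Golay
    smoothing, global compressibility slopes, and loop hysteresis at the
    half-maximum level, plus mono/biexponential decay kinetics of the
    minimum surface tension across cycles. Analyzes monolayer coordinate
    frames (GRO/PDB): leaflet assignment, area per lipid,
    liquid-condensed packing fractions by periodic DBSCAN clustering of
    acyl-chain marker atoms, chain tilt angles, phosphate-centered
    normalized density profiles, and partner-normalized heavy-atom
    contact counts versus monolayer area with replica aggregation. A
    synthetic-data module generates ground-truth-labeled traces, decay
    series, and monolayer frames for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'monosurf-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'sgolay.R'
    'trace-io.R'
    'surface-metrics.R'
    'decay-fit.R'
    'structure-io.R'
    'monolayer-structure.R'
    'synthetic-traces.R'
    'synthetic-monolayer.R'
    'pipeline.R'
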