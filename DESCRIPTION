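Package: mapkdyn
Title: Single-Cell Quantification of Oncogene-Driven ERK Signaling Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipeline for live-cell imaging studies of
    oncogene-driven ERK signaling in epithelial monolayers.  Converts
    per-cell tracking tables into kinase translocation reporter (KTR)
    activity traces, cleans them by coverage and tracking-quality rules,
    counts ERK activity pulses with Gaussian-refined extremum detection,
    and classifies single-cell dynamics as pulsatile, sustained or
    quiescent.  Quantifies directed migration of neighboring cells toward
    inducible-cell groups via windowed displacement angles, radial
    histograms and a subsampled two-sample Kolmogorov-Smirnov procedure;
    quantifies apical extrusion from multi-channel confocal z-stacks via
    Gaussian fits of z-intensity profiles and the delta-Z statistic; and
    computes EdU S-phase fold changes and shed-protein significance
    filters.  A seeded synthetic-data generator emulates every input
    modality with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'extrusion.R'
    'io.R'
    'methods.R'
    'migration.R'
    'peaks.R'
    'pipeline.R'
    'population.R'
    'sim-tables.R'
    'sim-traces.R'
    'sim-tracks.R'
    'sim-zstack.R'
    'trace-analysis.R'
    'utils.R'
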