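Package: thromboFlow
Title: Analysis and Simulation of Occlusive Thrombosis-on-a-Chip Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for occlusive thrombosis-on-a-chip
    microfluidic assays. Implements channel shear/flow design equations for
    rectangular perfusion chambers, gravimetric (balance-based) volumetric
    flow estimation, objective threshold-dwell occlusion-time detection with
    fixed-value censoring, maximum-intensity-projection integrated-density
    quantification of two-channel confocal z-stack time series, and the
    associated repeated-measures group statistics (two-way RM ANOVA with
    Tukey post hoc; Friedman with Dunn post hoc on censored occlusion times).
    A lumped-parameter hydraulic simulator generates complete synthetic
    experiments (single-channel embolism, pressure-relief occlusion, and
    EDTA-quenched designs, with graded anti-platelet drug effect) with ground
    truth, so every analysis stage can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    emmeans,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'deviceModel.R'
    'flowAnalysis.R'
    'imageQuant.R'
    'groupStats.R'
    'simulate.R'
    'stacksIO.R'
    'pipeline.R'
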