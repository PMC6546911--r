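Package: clampFRET
Title: Single-Molecule FRET Analysis of Sliding-Clamp Loading and Unloading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET experiments that
    resolve the intermediate states of a DNA sliding clamp (PCNA) as it is
    loaded onto and unloaded from DNA. Provides an exact stochastic
    (Gillespie) simulator of clamp kinetic schemes with Erlang sub-step
    structure, a photophysics renderer producing multi-donor fluorescence
    traces and two-channel movies with photobleaching and camera noise, spot
    detection and two-channel colocalization, trace quality control with
    photobleaching step counting and association/dissociation detection,
    maximum-likelihood Gaussian-emission hidden Markov modeling with
    information-criterion model selection, and kinetic summaries:
    synchronized FRET population heat maps, transition density plots, and
    dwell-time distributions with exponential and gamma fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'seeds.R'
    'simKinetics.R'
    'simPhotophysics.R'
    'spotDetection.R'
    'traceQC.R'
    'hmmInference.R'
    'kineticsAnalysis.R'
    'io.R'
    'pipeline.R'
    'plots.R'
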