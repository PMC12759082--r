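Package: DyeTrace
Title: Clonal Lineage Tree Reconstruction and Branching-Process Modelling
    from Dye-Dilution Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs clonal lineage trees of neocortical excitatory
    neurons from division-tracking dye (CFSE) fluorescence intensities,
    simulates radial glial progenitor lineages under a stochastic
    branching-process model of direct and indirect neurogenesis
    (mixture-Poisson clone sizes, Markov division-pattern transitions with
    boundary renormalisation), generates realistic synthetic observation
    tables (intensity-partition noise, inside-out radial positioning,
    marker-based neuron classes, apoptotic dropout, detection
    thresholding), and provides population-level clonal statistics
    (division-pattern summaries, exponential output decay, transition
    matrix estimation and tests, Kullback-Leibler comparison,
    zero-truncated Poisson mixture fitting, cumulative distance analysis)
    together with per-clone feature extraction and Ward clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'node-utils.R'
    'io.R'
    'config.R'
    'reconstruction.R'
    'simulator.R'
    'synthetic.R'
    'archetypes.R'
    'statistics.R'
    'features.R'
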