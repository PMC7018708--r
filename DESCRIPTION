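Package: qlmac
Title: Quorum-Licensing Dynamics of Macrophage TNF Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses density-dependent ("quorum-licensed")
    activation of macrophage populations stimulated with LPS. Implements a
    reduced ordinary-differential-equation model of NF-kB/IkB signalling with
    inducible TNF expression, secretion and autocrine/paracrine TNF feedback
    through a shared medium; Gaussian-mixture imputation of pre-stimulus
    reporter distributions across cell densities; a two-round multi-objective
    evolutionary calibration; and the downstream analyses (nadir-threshold
    bimodality statistics, permutation-tested correlations, mechanism
    sensitivity sweeps, parameter-robustness sweeps and
    heterogeneous-versus-homogeneous population comparisons), together with
    synthetic-data generators that emulate flow-cytometry snapshots and
    single-cell microscopy trajectories for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    mclust,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
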