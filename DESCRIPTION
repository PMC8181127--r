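Package: tpemet
Title: Target Populations of Environments and Selection Efficiency for
    Multi-Environment Wheat Trials
Version: 0.1.0
Authors@R:
    person("MET", "Tools", email = "met-tools@example.org", role = c("aut", "cre"))
Description: Tools for defining target populations of environments (TPEs) for
    a wheat breeding network from meteorological and soil covariates
    (20-day windowing, correlation-matrix PCA, Ward hierarchical
    clustering, thin-plate-spline surfaces), for multi-environment trial
    analysis by REML (variance components, broad-sense heritability,
    BLUEs and BLUPs for alpha-lattice trials), for quantifying direct and
    correlated response to selection from genetic correlations between
    selection environments and TPEs, for pedigree-based reaction-norm
    prediction with Hadamard-product covariance kernels fitted by Gibbs
    sampling, and for genetic-gain estimation by regression of pedigree
    BLUPs on trial year. Includes a synthetic-data generator that
    emulates an international elite spring wheat yield trial network with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
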