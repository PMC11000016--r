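Package: gatingnet
Title: Working-Memory Gating Analysis: Drift-Diffusion Modeling, Source
    Reconstruction, and Nonlinear Effective Connectivity
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying working-memory gating with
    the reference-back task: synthetic cohort and coupled-source generation
    with known ground truth, drift-diffusion simulation and maximum-likelihood
    fitting per Switching x Trial Type condition, Morlet time-frequency
    decomposition with decibel baseline normalization and cluster-based
    permutation testing, LCMV beamforming with DBSCAN voxel clustering and
    baseline-subtracted cluster signals, nonlinear multivariate autoregressive
    (neural-network) estimation of directed linear and nonlinear effective
    connectivity, and cross-validated nonlinear regression linking network
    connectivity to decision-model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'classes.R'
    'accessors.R'
    'utils.R'
    'synthetic-behavior.R'
    'synthetic-sources.R'
    'leadfield.R'
    'behavior-stats.R'
    'ddm-density.R'
    'ddm-simulate.R'
    'ddm-fit.R'
    'spectral-tfr.R'
    'spectral-cluster.R'
    'source-filter.R'
    'source-recon.R'
    'ncreann.R'
    'brain-behavior.R'
    'io.R'
    'pipeline.R'
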