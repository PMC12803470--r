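Package: swimHMM
Title: Hidden Markov State-Space Analysis of Zebrafish Locomotion and
    ARTR Population Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint state-space analysis of larval zebrafish exploratory
    locomotion and hindbrain ARTR population activity. Provides
    symmetry-constrained three-state hidden Markov models for swim-bout
    reorientation sequences (Normal forward / signed-Gamma turn emissions),
    Bernoulli-emission hidden Markov models for binarized neural rasters,
    threshold-based Markov-chain baselines, streak and stubbornness
    persistence statistics, neural-to-behavioral sojourn-time rescaling,
    neural-state-driven synthesis of planar swim trajectories with
    mean-square-reorientation diagnostics, individual phenotyping by
    likelihood confusion, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, HiddenMarkovModel, TimeCourse, Neuroscience,
    StatisticalMethod
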