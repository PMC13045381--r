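Package: openmsm
Title: Markov State Modelling of Membrane-Protein Opening with Adaptive Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterising the opening transition of a
    membrane-anchored multidomain protein (the sheddase ADAM10) from simulation
    data: FAST-style adaptive-sampling campaigns driven by a summed
    interdomain-distance reward, time-lagged independent component analysis
    (tICA) with Gaussian-mixture component screening and VAMP-2 scoring,
    k-means microstate clustering, reversible maximum-likelihood and Bayesian
    Markov state model estimation with implied-timescale and
    Chapman-Kolmogorov validation, PCCA+ coarse-graining into metastable
    macrostates with stationary populations and mean first-passage times, and
    structural observables (protein-lipid contacts, catalytic-site
    accessibility, antibody-membrane clash). A synthetic-dynamics module
    generates hidden-macrostate trajectories with state-conditioned Gaussian
    emissions so that every stage of the pipeline is testable without
    molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    mclust,
    igraph,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
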