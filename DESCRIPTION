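Package: bayesmeg
Title: Variational Bayesian MEG Source Reconstruction with Empirical Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for magnetoencephalography (MEG) source reconstruction
    under a common empirical-Bayes covariance-component framework.  Four
    prior schemes -- a Bayesian minimum-norm model (MNM), an empirical
    Bayesian beamformer (EBB), and two multiple-sparse-priors schemes
    (automatic relevance determination, ARD, and greedy search, GS) -- are
    optimized by restricted maximum likelihood (ReML) against a Laplace
    free-energy objective.  The package ships a fully synthetic study
    bench: a seeded wrinkled-sphere cortical mesh inside a spherical
    conductor, a single-sphere (Sarvas) forward model, a dipole simulator
    with controlled source correlation and sensor noise, and FROC-style
    spatial (SAI) and temporal (TAI) accuracy metrics for comparing the
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
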