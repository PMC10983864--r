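Package: decoupnoise
Title: Decoupling Noise in Genotype Frequency Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulators and estimators for populations whose
    genotype frequencies fluctuate far beyond classical genetic drift
    because offspring numbers are correlated within genotypes more than
    between them ("decoupling noise"). Provides exact first- and
    second-moment predictions from an effective offspring-covariance
    model, correlated-noise Langevin and coupled logistic-map simulators,
    diffusion-theory predictions for fixation probabilities and site
    frequency spectra, Taylor's-law mean-variance scaling statistics,
    chaos diagnostics (variance-growth and nearest-neighbour Lyapunov
    exponents), and a Bayesian hierarchical partition of intrinsic
    versus extrinsic decoupling noise, together with synthetic-data
    generators emulating split-replicate culture experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
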