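Package: movegp
Title: Hierarchical Non-Stationary Gaussian Process Models for Animal Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous-time animal-movement modelling with multilevel
    Gaussian processes. Telemetry trajectories (positions or velocities) are
    modelled as Ornstein-Uhlenbeck-type Gaussian processes whose movement
    parameters -- noise amplitude, correlation lengthscale and mean location
    -- may themselves vary continuously in time as latent lower-level
    Gaussian processes with periodic or quasi-periodic covariance kernels.
    Inference uses an adaptive Metropolis-adjusted Langevin sampler in
    whitened coordinates, with trajectory segmentation into local Gaussian
    process experts for scalability, Gelman-Rubin and effective-sample-size
    diagnostics, gradient-based hyperparameter optimization, synthetic
    trajectory generators for validation, and posterior predictive checks on
    step-length and turn-angle distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
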