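Package: sptdiff
Title: Diffusion Analysis of Single-Particle Tracking Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-dimensional single-particle tracking data from
    quantum-dot-tagged membrane proteins. Computes time-averaged mean square
    displacement curves, short-lag and anomalous-exponent diffusion fits, and
    maximum-likelihood diffusion coefficients that account for static
    localization error and camera motion blur. Classifies trajectories as
    immobile, restricted or free with a relative-deviation statistic whose
    percentile boundaries are calibrated by Brownian random-walk simulation.
    Segments trajectories into discrete diffusive states with a
    Gaussian-displacement hidden Markov model, and summarises groups of tracks
    with median/interquartile statistics and nonparametric two-sample tests.
    Includes simulators for Brownian, confined, directed, immobile and
    state-switching motion with localization noise and fluorophore blinking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
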