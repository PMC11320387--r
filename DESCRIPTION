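Package: gelrelease
Title: Release Kinetics of Small Molecules from Collapsed Microgels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the diffusive release of nonionic sub-nanometer cargo
    molecules from a collapsed spherical microgel particle using dynamical
    density functional theory (DDFT) in spherical symmetry. Provides the
    molecule-parameterization layer (gyration-tensor shape anisotropy,
    exponential size dependence of the in-gel diffusion coefficient,
    surface-area model for the transfer free energy), a conservative
    finite-volume Smoluchowski solver on a nonuniform radial grid with
    explicit and implicit time stepping, Weibull master-curve utilities for
    release profiles, and closed-form mean-first-passage-time predictors for
    the half-release time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
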