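Package: fretmd
Title: FRET Observables and Looping Kinetics from Peptide MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fluorophore-labeled peptide molecular
    dynamics trajectories: donor-acceptor end-to-end distances and the
    FRET orientational factor kappa-squared, skewed-Gaussian distance
    distribution fits, Boltzmann-inversion free-energy landscapes over
    (Rg, SASA), Daura RMSD conformational clustering, first-contact-time
    looping kinetics with sink-radius optimization and solvent-viscosity
    correction, time-series indicators (autocorrelation time, rescaled-range
    Hurst exponent, Welch spectral exponent with noise classification), and
    shear-viscosity extraction from periodic cosine-perturbation velocity
    profiles. Includes seeded synthetic-data generators (Ornstein-Uhlenbeck
    traces, fractional Gaussian noise, power-law noise, bead-chain
    trajectories) so every stage is testable without microsecond MD output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
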