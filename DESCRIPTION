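Package: nucspt
Title: Single-Molecule Tracking Simulation and Kinetic Analysis of Nuclear Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Tools for quantifying the nuclear dynamics of chromatin-binding
    proteins from live-cell single-molecule tracking (SMT). Provides a
    Brownian-dynamics forward model of a nuclear factor with three-state
    binding kinetics (free, short-lived bound, long-lived bound) inside a
    reflecting nucleus, with camera photophysics (localization error,
    photobleaching, motion-blur loss of mobile molecules at slow frame
    rates) and optional heterochromatin subdomains; maximum-displacement
    gated trajectory linking with optimal per-frame-pair assignment;
    per-molecule apparent diffusion coefficients from mean squared
    displacement fits; per-cell two-state (bound/free) kinetic fits of the
    jump-length distribution; residence-time analysis by double-exponential
    fits of track-duration survival curves; spatial stratification of
    tracks into euchromatin and heterochromatin; and study-level
    orchestration with the statistical comparisons used in the field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
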