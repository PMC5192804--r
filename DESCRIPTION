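Package: thermalwind
Title: Horizontal Wind Estimation from Thermalling Flight in GPS Bird Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates horizontal wind velocity, with a full error covariance,
    from short high-frequency (1 Hz) GPS segments of birds circling in
    thermals. Scalar airspeed along the wind-compensated track is modelled as
    a first-order autoregressive process; the wind vector is the
    maximum-likelihood drift that minimises the unexplained airspeed variance
    over an 18-second circling window, and the error covariance follows from
    the Hessian of the profile likelihood. Also provides circling-event
    detection, per-event flight characteristics (banking angle, lift and drag
    coefficients, sink rate, thermal strength) with default white-stork
    aerodynamics, vertical thermal profiling, pairwise calibration
    diagnostics, and a synthetic thermalling-track simulator with known truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
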