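Package: ftleforage
Title: Lagrangian Coherent Structures and Predator Foraging Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links submesoscale aggregative surface-current features to marine
    predator habitat selection and feeding rates. Computes backward-in-time
    finite-time Lyapunov exponent (FTLE) fields from gridded surface currents
    by adaptive Runge-Kutta-Fehlberg tracer advection, turns 1 Hz biologging
    depth traces, lunge events and GPS fixes into located, FTLE-matched dive
    records, and provides use-availability tests (weighted Kolmogorov-Smirnov),
    mixed-model feeding-site selection with correlated-random-walk and
    time-shift null models, and a supervised covariate-dependent Markov model
    of feeding intensity with stationary-probability feeding-rate curves.
    Includes analytic benchmark flows and a whale-deployment simulator with
    known coupling coefficients so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    grDevices,
    MASS,
    nlme,
    geosphere,
    generics,
    withr
Suggests:
    ncdf4,
    nnet,
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
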