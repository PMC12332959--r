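Package: viewdecode
Title: Time-Resolved Population Decoding of View-Invariant Object
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for time-resolved decoding of object identity from
    populations of inferotemporal-cortex-like spiking neurons. The package
    simulates inhomogeneous Poisson spike trains with view-specific and
    view-invariant object tuning, converts spike events to sliding-window
    rates with baseline subtraction and per-cell z-normalization, screens
    cells for stimulus responsiveness, assembles pseudo-population response
    vectors, trains one-vs-rest linear support vector machines at anchor
    viewing angles and tests them at rotated angles, scores performance with
    the d-prime statistic against a random-labeling permutation null, detects
    significant time intervals with a consecutive-bin rule, and estimates
    decoding performance as a function of population size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
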