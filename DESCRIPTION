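Package: cscstab
Title: Cell-Fate Probability Corridors and Underlying-Field Factors for
    Cancer Stem Cell Population Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the stabilization of the cancer stem cell (CSC) fraction
    in a cultured cancer cell population with a two-compartment
    (stem/non-stem) ordinary differential equation model whose division,
    transition and death scenarios occur with prescribed probabilities.
    Provides the inverse machinery to recover, from a measured stem-cell
    fraction curve s(t) and constant division/death rates, time-varying
    corridors (pointwise envelopes) of the six cell-fate scenario
    probabilities under a minimal-change principle; decomposes recovered
    probability trajectories onto a small set of bump-shaped secreted
    "underlying field" factor kinetics by pseudo-time gradient relaxation;
    and ranks attributions of each factor to stem cells, non-stem cells or
    neither by refitting under cell-kinetics-modulated bases.  Includes a
    synthetic-data generator (parametric stabilization curves and
    forward-simulated curves with known ground truth) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
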