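Package: knotdna
Title: Knot Statistics in Coarse-Grained Double-Stranded DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation and topological analysis of double-stranded
    DNA modelled as a semi-flexible, self-avoiding bead chain (a discrete
    Kratky-Porod model with hard-sphere excluded volume). Provides a Metropolis
    sampler with pivot, crank-shaft and generalized MOS moves; knot detection
    in open chains via centre-of-mass triangle closure, topology-preserving
    chain reduction and Alexander polynomial determinants; knot localization
    and size statistics by end trimming; and calibration of the bending
    stiffness and effective chain diameter against experimental knotting
    probabilities through a local-regression probability surface and
    Levenberg-Marquardt least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
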