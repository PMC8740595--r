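Package: gutfix
Title: Neutral Mutant Fixation in a Flow-Structured Gut Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic modelling of bacterial population
    dynamics in the lumen of the colon, represented as a one-dimensional
    segment with net flow, effective diffusion and Monod-limited growth on a
    single inflowing food source. Provides a conservative finite-volume
    solver for the coupled food/wild-type/mutant concentration fields,
    steady-state detection, washout phase diagrams, neutral-mutant fixation
    probabilities computed both by direct integration and by the adjoint
    zero mode of the linearised mutant dynamics, active-population analysis,
    and an individual-based stochastic counterpart used to validate the
    deterministic fixation probabilities at reduced population scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
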