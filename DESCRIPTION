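Package: cyanogate
Title: Circadian Gating of Cell Size Control in Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling and inference of circadian-clock-modulated
    cell size control in Synechococcus elongatus. Provides an exact thinning
    simulator of growing and dividing single-cell lineages whose division rate
    is the product of a size-control hazard, a periodic circadian coupling
    function, and the instantaneous elongation rate; deterministic models of
    constant and graded light-dark environments; maximum-likelihood estimation
    of size-control parameters from birth/division tables; Bayesian inference
    of the periodic coupling function from single-cell length traces or from
    division times alone; and population analyses (subpopulation clustering,
    size-control classification, division-time windows) under constant light
    and graded light-dark cycles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
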