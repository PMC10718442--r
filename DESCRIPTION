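Package: crashdecluster
Title: Declustering Highway Crash Catalogs with Temporal Self-Exciting Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits temporal Hawkes (self-exciting) point-process models to
    event catalogs such as highway crash records, separating a background
    ("primary") rate from exponentially decaying excitation that generates
    triggered ("secondary") events. Supports stationary, piecewise-constant
    (day-of-week or rush-hour) and sinusoidal periodic background rates,
    exact maximum-likelihood estimation with analytic gradients, AIC model
    comparison, stochastic declustering into per-event triggering
    probabilities, queue-time extraction from the fitted decay rate, spatial
    corridor filtering of geocoded catalogs, and exact simulators (Ogata
    thinning and cluster/branching) for validation with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
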