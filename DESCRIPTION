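Package: h2kinetics
Title: Kinetic Analysis of Batch Dark-Fermentation Biohydrogen Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic analysis of cumulative biohydrogen production
    curves from batch dark fermentation. Fits the modified Gompertz model
    (maximum production Hmax, maximum rate Rmax, lag phase lambda) to
    replicate gas-volume time series by bounded nonlinear least squares with
    data-driven initialization, derives the analytical production-rate curve
    and the time to any production fraction (t95), and estimates Monod growth
    parameters (mumax, Ks) from specific-growth-rate data. Computes the
    standard process metrics (substrate yield, volumetric productivity,
    substrate uptake rate, relative improvement between substrates), builds
    screening-style kinetic report tables, and generates synthetic
    gas-production and growth data with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
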