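Package: hccalloc
Title: Tumor-Size Threshold Optimization for Liver-Graft Allocation in
    Hepatocellular Carcinoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic waiting-list model of liver-graft allocation to
    hepatocellular-carcinoma patients. Tumor size at presentation follows an
    exponential distribution; mortality hazards of transplanted and
    non-transplanted patients depend on size; expected five-year survivor and
    death counts are obtained by adaptive quadrature of the survival
    integrals. The package locates the transplantation size threshold that
    minimizes total mortality, the equivalent threshold whose mortality
    matches the Milan 5 cm cutoff, Milan-criteria allocation proportions and
    graft utilization, and provides an individual-based Monte-Carlo cohort
    simulator as an independent stochastic check, plus an exponential fitter
    for observed tumor-size samples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
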