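Package: mutdyn
Title: Phase-Plane Analysis and Qualitative Classification of Two-Species
    Mutualism Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A registry of classical two-species mutualism population models
    (Lotka-Volterra linear-benefit forms, saturating-benefit forms,
    cost-benefit and consumer-resource formulations) together with generic
    template models organised by the kind of intraspecific density
    dependence they assume.  Provides phase-plane machinery (nullcline
    extraction, equilibrium finding and local stability typing, basin-of-
    attraction mapping, separatrix tracing, oscillation detection) and a
    classifier that assigns any parameterised model to a qualitative-outcome
    taxonomy: stable coexistence, unbounded growth, extinction, partner-
    density thresholds, Allee effects, and overexploitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
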