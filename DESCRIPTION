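Package: fishcat
Title: Object Categorization Analysis for Two-Alternative Choice
    Experiments in Archerfish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for analysing visual object categorization
    in two-alternative choice experiments of the kind used with archerfish.
    Generates parametric animal-like and plant-like grayscale stimuli with
    controllable shape and texture statistics, extracts a panel of 18
    classical shape, curvature, texture, template-correlation, symmetry and
    energy descriptors from object-on-white images, trains and greedily
    orders features for a support-vector-machine categorizer under a
    repeated random-split protocol, simulates paired-presentation decisions
    with calibrated execution noise, and evaluates behavioural success
    rates with a hierarchical beta-binomial Bayesian model using highest
    density intervals and regions of practical equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    class,
    png,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
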