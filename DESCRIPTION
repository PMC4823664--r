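Package: odormix
Title: Dose-Response Modelling of Olfactory Sensory Neuron Responses to Odor Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the response of olfactory sensory neurons (OSNs) to single
    odors and odor mixtures with a generalized Hill equation in which the Hill
    coefficient, efficacy and midpoint are properties of the odor-receptor
    pair. Provides the mixture composition law, reduction of fixed-ratio
    mixtures to effective sigmoids, classification of mixture behaviors
    (suppression, hypoadditivity, synergy, inhibition, overshadowing),
    experimental-protocol adapters, nonlinear fitting of single-odor curves
    with mixture prediction, and the three-dimensional odor-response-space
    algebra: scaling, composition, embedding, basis decomposition, convex-hull
    coverage and target-odor synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
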