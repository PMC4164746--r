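Package: dorsalhorn
Title: Simulation and Quantification of Synaptic Bouton Density in the Spinal Dorsal Horn
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and quantify fluorescently labelled synaptic
    boutons (IB4-binding non-peptidergic afferent terminals and GAD65
    immunoreactive inhibitory terminals) in laminae I and II of the rat spinal
    dorsal horn, together with the behavioural endpoints used in cuff models of
    neuropathic pain. Includes a seeded synthetic-data generator (section
    geometry, spatial Poisson puncta fields, two-channel 12-bit micrograph
    rendering, von Frey up-down staircases, Hargreaves latencies), a puncta
    detection pipeline (top-hat contrast accentuation, connected-component
    segmentation with a minimum-size filter, mean-area overlap correction),
    anatomical ROI placement with contralateral mirroring, the Dixon up-down
    50 percent withdrawal-threshold estimator, and cohort statistics
    (percent-of-sham normalisation, group comparisons, phase-wise Spearman
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
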