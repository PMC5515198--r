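Package: metachain
Title: Markov Chain Modelling of Metastatic Breast Cancer Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates discrete-time Markov chain models of metastatic
    progression from longitudinal breast cancer cohorts. Patient event
    histories are reduced to ordered metastatic pathways, site-to-site
    transition probabilities are estimated by direct enumeration of
    progression events, and the fitted chain supports state-vector
    propagation, conditional next-site distributions, classification of
    anatomical sites as spreaders or sponges from two-step pathway
    probabilities, Kaplan-Meier survival analysis grouped by first
    metastatic site, Weibull fits to time-to-metastasis distributions, and
    ring-diagram (sunburst) aggregation of pathways. A seeded synthetic
    cohort generator simulates timed random walks on a configured
    transition graph, with right-censoring and co-occurring metastases, so
    the full pipeline can be exercised without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
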