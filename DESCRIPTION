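Package: epimediate
Title: Co-Methylation Networks and Causal Mediation Linking Social Adversity
    to Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for blood DNA-methylation studies
    of adverse social exposures and fronto-limbic brain morphometry.
    Transforms beta-values to M-values, filters EPIC-style probes (sex
    chromosomes, cross-reactive probes, blood-brain correlated subsets),
    estimates leukocyte composition by reference-based constrained
    deconvolution, residualizes probes against covariates, builds weighted
    co-methylation networks with soft-threshold selection and topological
    overlap clustering, extracts module eigengenes, runs standardized
    three-arm regression screens with Benjamini-Hochberg control,
    performs quasi-Bayesian Monte Carlo causal mediation with mediator
    classification and probe-wise follow-up, and tests gene-set
    over-representation of exposure-associated probes. Ships a synthetic
    cohort generator with planted modules and mediation paths so every
    stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    limma,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
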