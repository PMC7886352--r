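Package: lymphkin
Title: Lymphocyte Turnover Kinetics from In Vivo Heavy-Water Labeling
Version: 0.1.0
Authors@R:
    person("P.", "Janssen", email = "pjanssen@example.org",
           role = c("aut", "cre"))
Description: Quantifies production and loss rates of T- and B-cell subsets
    from stable-isotope (deuterated water) labeling studies. Implements the
    body-water enrichment curve, multi-exponential DNA label-enrichment
    models with granulocyte-based scaling, joint maximum-likelihood fitting
    of enrichment and cell-number data, model selection between one and two
    kinetic subpopulations, residual-bootstrap confidence intervals,
    excision-circle (TREC/KREC) calculations, nonparametric cohort
    comparisons, and a synthetic-cohort generator with known ground truth
    plus a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
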