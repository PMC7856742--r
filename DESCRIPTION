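Package: ebccea
Title: Cost-Effectiveness Analysis of Surgical Strategies for Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing the long-term
    cost-effectiveness of three surgical strategies for early breast cancer
    (mastectomy, breast-conserving therapy, and mastectomy with
    reconstruction). Implements synthetic patient-level cohort generation,
    multinomial propensity-score matching with balance diagnostics,
    competing-risks cumulative-incidence estimation with a permutation Gray
    test, conversion of cumulative incidences to annual transition
    probabilities, a discounted four-state Markov cohort model with
    first-year tunnel states and half-cycle correction, incremental
    cost-effectiveness analysis with extended-dominance handling, and
    one-way plus probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    cmprsk,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
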