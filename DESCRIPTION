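Package: rareboneqol
Title: Quality of Life and Cost-Utility Simulation for Rare Bone Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing EQ-5D-5L health-related quality-of-life data
    from adults with rare bone diseases (osteogenesis imperfecta, fibrous
    dysplasia and X-linked hypophosphatemia) and for simulating the
    cost-utility of a hypothetical treatment. Provides value-set scoring of
    EQ-5D-5L health states, descriptive and exact inferential statistics
    (Fisher's exact r x c test, one-way ANOVA, linear regression), a seeded
    synthetic-cohort generator calibrated to published summary statistics, a
    10-year two-arm discounted QALY simulation with attainment sensitivity
    analysis, and willingness-to-pay tables across cost-effectiveness
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
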