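Package: painmod
Title: Responder Phenotyping for Endogenous Pain-Modulation Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of continuous visual-analogue-scale (VAS)
    pain-rating series from placebo analgesia, conditioned pain modulation and
    offset analgesia experiments. Reduces continuous ratings to per-stimulus
    block means, classifies each participant as inhibitor, nonresponder or
    facilitator with a bootstrapped resampling test (including an
    exact-enumeration oracle for the bootstrap p-values), and computes
    cohort-level statistics: paired effect sizes, percent pain change, rating
    variability, two-proportion tests, normality-gated group comparisons with
    Bonferroni correction, and one-way ANOVA with post hoc t-tests. A synthetic
    cohort generator with a documented hierarchical noise model makes the whole
    pipeline testable without human data.
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
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
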