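Package: crabacid
Title: Cohort Analysis of Ocean-Acidification Effects on Juvenile Crabs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for long-term ocean-acidification rearing
    experiments on juvenile crabs: interval-censored exponential mortality
    models selected by AICc, degree-day exponential wet-mass growth models
    with per-crab intercepts, linear carapace growth with nested ANCOVA,
    principal component analysis of carapace morphometrics, terminal
    condition-index and calcification endpoint tests, and a closed-form
    seawater CO2-system solver. A seeded synthetic-cohort generator emulates
    the full experimental design (seasonal temperature forcing, daily death
    censuses, degree-day molt clocks, correlated landmark measurements) so
    that every fitting routine can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
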