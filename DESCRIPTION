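Package: lifeyears
Title: Period Life Tables, Cause-Deleted Life Expectancy and Years of Life
    Lost with Latin Hypercube Uncertainty Intervals
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds complete period life tables from vital-registration death
    records and registry population counts, derives cause-deleted life tables
    by proportional cause elimination and years of life lost (YLL) at ages 0,
    40 and 65 for ICD-10 cause-of-death groups, and attaches 95% uncertainty
    intervals via Latin hypercube Monte Carlo sampling of annual variation in
    populations and crude mortality rates. Includes district-level
    effect-size analysis (Pearson and point-biserial correlations with pooled
    two-sample t tests) comparing evacuation and non-evacuation districts, a
    synthetic vital-registration generator with Gompertz-Makeham mortality
    for validation, and an end-to-end pipeline driven by a YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
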