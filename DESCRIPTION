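Package: phenokarst
Title: Thermokarst Microtopography and High-Arctic Plant Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the effect of ice-wedge thermokarst
    microtopography on high-Arctic plant phenology. Computes thaw degree
    days (TDD) and phenophase-specific cumulative TDD from hourly soil
    temperature series, abundance-weighted community phenophase dates with
    fixed and specific species averages, unbalanced two-way type II
    ANOVA/ANCOVA with Tukey-adjusted estimated marginal mean contrasts, and
    the decomposition of phenological variation into species-turnover,
    intraspecific, and covariation sums of squares. Includes a seedable
    synthetic-landscape generator emulating a 2x2 polygon top/trough by
    control/thermokarst sampling design so the whole chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
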