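Package: reradscore
Title: Survival Prediction Scores for Palliative Reirradiation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying actuarial point scores that
    predict survival after palliative reirradiation. Implements Kaplan-Meier
    estimation with Greenwood variance, k-group and pairwise log-rank tests,
    Cox proportional-hazards regression (Breslow ties, Newton-Raphson) with a
    univariate log-rank screen and likelihood-ratio backward elimination, the
    death-rate-divided-by-ten point-table constructor in its 1-month and
    2-month variants, four-tier risk grouping, and the three-variable survival
    prediction score (SPS) comparator. Includes a seeded synthetic-cohort
    generator emulating the covariate mix and survival structure of a
    reirradiation service, CSV round-tripping with explicit missing-data
    semantics, and an end-to-end pipeline that writes a reproducible report
    bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
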