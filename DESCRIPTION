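Package: habitcoach
Title: Rule-Based Decision Support for Children's Healthy-Habit Coaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale decision-support engine for behavioural coaching of
    school-age children (9-12 years). Classifies anthropometrics against an
    LMS growth reference (BMI-for-age z-scores, five nutritional statuses),
    scores food-frequency and PAQ-C questionnaires, stratifies every monitored
    behaviour into green/yellow/red risk flags, detects unhealthy behavioural
    trends in daily wearable series (seasonal adjustment, exact piecewise
    linear regression, slope classification and forecasting), and generates
    weekly three-mission personalised coaching plans with red-history
    prioritisation, carer validation and ability-point accounting. A seeded
    synthetic-cohort simulator with known ground truth makes the whole
    pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
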