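Package: dashtrack
Title: DASH Adherence Scoring, Tailored Feedback, and Trial Analytics for
    App-Based Diet Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for nutrient-based Dietary Approaches to Stop Hypertension
    (DASH) adherence assessment from daily diet-tracking logs and 24-hour
    dietary recalls. Standardizes nutrient intakes to calorie-relative bases,
    scores the nine-component DASH adherence index (0-9, half-point credits),
    composes and schedules tailored feedback text messages, summarizes
    self-monitoring engagement (valid tracked days, weekly trends via mixed
    models), applies dietary-recall validity rules, and runs
    baseline-adjusted randomized-trial analyses. Includes a synthetic-cohort
    simulator (permuted-block randomization, intake generation matched to a
    latent adherence level, declining tracking engagement, blood pressure
    coupled to adherence change) so every analysis path can be exercised and
    validated by parameter recovery without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
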