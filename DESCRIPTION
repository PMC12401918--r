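Package: homedrift
Title: Behavioral Drift Detection from Smart-Home Activity Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects behavioral anomalies suggestive of early neurodegeneration
    from annotated smart-home event logs. Reads CASAS-dialect sensor logs,
    aggregates labeled activity intervals into daily time budgets, and scores
    each day with a weighted activity deviation index (the weighted sum of
    absolute differences between a day's activity proportions and a reference
    routine). Nightly sleep sessions are summarized by onset, duration and
    interruption metrics and combined into a weighted sleep deviation score.
    Days are flagged against fixed or dynamic (mean plus a multiple of the
    standard deviation) thresholds, and cross-score analyses report flag
    overlap, night-time activity counts and long-duration appliance episodes.
    A deterministic synthetic-home generator produces labeled event streams
    with injectable anomalies and ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
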