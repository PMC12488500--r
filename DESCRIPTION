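Package: doughnut
Title: Monitoring Social Shortfall and Ecological Overshoot Against the
    Doughnut of Social and Planetary Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor human wellbeing and planetary health with the
    doughnut-shaped framework of social and planetary boundaries: a validated
    registry of social-foundation and ecological-ceiling indicators,
    normalization of raw indicator values into boundary-relative shortfall and
    overshoot percentages, autocorrelation-robust linear trend estimation,
    linear elimination-pathway scenarios to 2030 (social) and 2050
    (ecological), disaggregation into income-based country clusters with
    fair-share footprint attribution, radial doughnut and bar-chart views, and
    a seeded synthetic-world generator so the whole pipeline is testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
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
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
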