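Package: dcea
Title: Aggregate Distributional Cost-Effectiveness Analysis for Health
    Benefits Packages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregate distributional cost-effectiveness
    analysis (DCEA) of health benefits packages in data-constrained
    settings. Converts intervention-level cost-effectiveness inputs and
    survey-derived socioeconomic distributions into per-subgroup net
    health benefit in DALYs, builds per-subgroup abridged lifetables and
    Sullivan-method health-adjusted life expectancy, values inequality
    with the Atkinson index and equally distributed equivalent (EDE)
    health, places interventions on the health equity impact plane, and
    runs declarative scenario sensitivity analyses. Includes a synthetic
    household-survey generator with controllable socioeconomic gradients
    so the full pipeline is testable without microdata access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
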