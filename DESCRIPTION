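Package: rationplan
Title: Least-Cost Ration and Menu Formulation for Supplementary
    Nutrition Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Formulates least-cost take-home rations (raw food baskets)
    and hot-cooked-meal menus for supplementary nutrition program
    beneficiaries (children, severely acutely malnourished children,
    pregnant and lactating women) under program rules: macronutrient
    guideline bands, tolerable upper limits, food-group inclusion,
    cereal-to-pulse ratios, per-item quantity windows, subsidised
    prices, fortification overlays, and a daily budget. Solves the
    underlying mixed-integer linear programs with an exact
    branch-and-bound over simplex relaxations, enumerates next-least-
    expensive alternative baskets via no-good cuts, and reports
    nutrient-adequacy analytics (percent-of-guideline tables,
    colour-coded adequacy, food-group allocations, radar ratios,
    weekly macro series).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
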