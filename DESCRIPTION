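Package: mhfii
Title: Diet Quality and Food Insecurity with the Modified Healthy Food
    Intake Index
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs the modified Healthy Food Intake Index (mHFII), an
    11-component diet-quality score (0-18) built from 52-item food frequency
    questionnaire (FFQ) responses, and categorises individual-level food
    insecurity with the nine-item Household Food Insecurity Access Scale
    (HFIAS). Includes a calibrated synthetic survey-cohort generator with
    controlled sociodemographic confounding, and inference tools estimating
    the association between food insecurity and diet quality: one-way and
    covariate-adjusted ANOVA contrasts against a food-secure reference with
    Bonferroni correction, confounder screening, and per-food-group
    proportional-odds ordinal regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
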