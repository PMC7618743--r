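Package: shelfnudge
Title: Simulation and Analysis of Positioning and Labelling Interventions
    in an Online Supermarket
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse randomised controlled trials of
    choice-architecture interventions in an experimental online supermarket.
    Generates seedable synthetic product catalogs with realistic raw-data
    quirks, cleans nutrient declarations, computes FSAm-NPS (Nutri-Score)
    health scores and a four-indicator environmental composite score,
    implements label-biased shelf ordering with pagination, simulates
    shopping sessions under a position- and label-sensitive discrete choice
    model, applies pre-registered exclusion and compliance rules, and runs
    the full statistical pipeline: primary linear regressions (log-transformed
    and exponentiated for environmental outcomes), IQR-outlier and
    full-compliance sensitivity analyses, secondary nutrient and
    environmental-indicator models, demographic interaction models,
    Levene-gated ANOVA with Tukey or Games-Howell post-hoc tests for basket
    price, spill-over models, and noncentral-t sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
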