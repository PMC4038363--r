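Package: melrisk
Title: Individual 5-Year Absolute Risk of Cutaneous Melanoma in New Zealand
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-control relative-risk modelling and Gail-type absolute risk
    projection for cutaneous melanoma in the fair-skinned New Zealand
    population. Provides sex-specific logistic risk models (univariate
    screening, backward/forward selection, bootstrap selection stability),
    the Bruzzi case-based attributable-risk estimator with bootstrap
    uncertainty, and projection of individual 5-year absolute melanoma risk
    from regional age- and sex-specific incidence under competing
    non-melanoma mortality, using a piecewise-constant two-cause hazard
    model. Ships the regional rate tables and published odds-ratio parameter
    sets, a seedable synthetic case-control cohort generator for testing the
    full pipeline, and internal-validation statistics (C-statistic,
    Hosmer-Lemeshow calibration, classification metrics, linktest).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
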