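Package: equicover
Title: Socio-Economic Inequity in Health-Service Coverage from Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures socio-economic inequality in health-service coverage and
    health status from complex household-survey microdata. Builds an
    asset-based wealth index by multiple correspondence analysis and assigns
    weighted quantile groups; computes design-aware weighted prevalences with
    linearised standard errors, Rao-Scott corrected association tests, and
    survey-weighted logistic regression with backward elimination; and
    derives the standard equity indices: absolute gaps, the slope and
    relative indices of inequality from midpoint (ridit) rank scores, and
    the concentration curve and index. A synthetic multistage stratified
    survey generator with known inequality parameters supports validation
    without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
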