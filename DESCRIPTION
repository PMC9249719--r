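Package: ssbtrends
Title: Adolescent Sugary-Drink Consumption Trends by Race and Neighborhood Food Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for repeated cross-sectional analyses of adolescent
    sugary-drink consumption surveys. Converts beverage frequency-and-container
    survey responses into daily-consumer status and estimated daily calories,
    classifies school attendance zones as providing high or low exposure to
    unhealthy food retail (fast food, convenience stores, gas stations) using
    an in-sample-mean establishment-count threshold, and estimates wave-specific
    prevalence and mean calories with school random intercepts, cluster-robust
    standard errors, and Bonferroni-corrected contrasts against baseline,
    overall and stratified by race/ethnicity and retail exposure. Ships a
    calibrated synthetic cohort generator (schools, attendance zones, retail
    establishments, and survey responses) so the full pipeline can be exercised
    and validated without access to restricted district survey or commercial
    establishment data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    mgcv,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
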