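Package: utciproxy
Title: Hourly Reanalysis UTCI as a Proxy for In-Situ Measurements in
    Outdoor Thermal Comfort Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating hourly reanalysis-style Universal Thermal
    Climate Index (UTCI) series as a stand-in for synchronous on-site
    measurements during outdoor thermal comfort (OTC) questionnaire surveys.
    Computes UTCI from raw meteorological inputs via the operational
    sixth-order polynomial approximation, mean radiant temperature from
    globe-thermometer readings (forced-convection equation) or from solar
    and thermal radiation fluxes, and Dynamic Thermal Sensation (DTS) from
    UTCI. Pairs survey votes with hourly proxy data by nearest-hour
    rounding, quantifies proxy-versus-in-situ agreement (bias, spread,
    correlation, balanced-subset ANOVA, thermal-stress stratification), and
    derives neutral temperatures and comfort ranges from binned mean
    thermal sensation votes. Includes a seeded synthetic-campaign generator
    emulating a subtropical survey setting so the full analysis is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
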