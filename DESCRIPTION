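Package: wheatmoist
Title: Winter Wheat Yield Responses to Moisture Variation via Multi-Scalar SPEI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline quantifying how rain-fed winter wheat yields
    respond to drought and wetness. Computes the Standardized Precipitation
    Evapotranspiration Index (SPEI) at multiple time scales from monthly
    temperature and precipitation panels (Thornthwaite potential
    evapotranspiration, climatic water balance, log-logistic L-moment fitting,
    inverse-normal standardization), detects trends with the Mann-Kendall test
    and Sen's slope, links detrended yields to growth-stage SPEI through
    Pearson correlation tables, and estimates a quadratic fixed-effects panel
    model with AR(1) errors from which optimum moisture, loss thresholds and a
    moisture-level yield-response table are derived. Includes a synthetic
    climate and yield generator so the full pipeline is testable without
    external station data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
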