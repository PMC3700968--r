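Package: frosthatch
Title: Winter Soil Temperature Simulation Under Snow and Crop Residue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Point-scale simulation of winter 10 cm soil temperatures under
    bare-soil versus prostrate crop-residue management, built around an hourly
    surface energy balance and one-dimensional heat conduction through a
    snow-residue-soil stack with soil freezing and thawing. Includes a
    synthetic daily weather generator for mid-latitude continental winters
    (seasonal cycle, autoregressive anomalies, Arctic cold outbreaks), hourly
    disaggregation, a field-capacity bucket soil water model, and the risk
    statistics used to assess miscanthus rhizome winterkill: annual extreme
    minima of the 3-day running-mean 10 cm temperature, exceedance frequencies
    at lethal thresholds (-3.5 C, -6.0 C), residue-thickness response curves,
    quadratic bias correction against observations, and linear trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
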