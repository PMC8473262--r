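Package: lakechla
Title: High-Frequency Chlorophyll-a Monitoring Analysis for Shallow Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fixed-station hyperspectral monitoring of
    chlorophyll-a in shallow eutrophic lakes. Converts remote-sensing
    reflectance spectra to chlorophyll-a with a turbid-water red/NIR band-ratio
    algorithm, derives daily and seven-day antecedent meteorological features,
    detects heatwave-terminating temperature drops, clusters relativized diel
    chlorophyll profiles (Sorensen distance, flexible-beta linkage), classifies
    cluster membership from environmental drivers by multinomial logistic
    regression with Wald tests, and models seasonal chlorophyll-weather
    response surfaces by Nonparametric Multiplicative Regression (local-mean
    Gaussian kernels, cross-validated R-squared, sensitivity analysis,
    permutation tests). Includes a multi-site synthetic scenario generator so
    every stage is testable without station data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
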