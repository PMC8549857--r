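Package: lichenrisk
Title: Critical Loads and Ecological Risk for Epiphytic Macrolichens
    Under Nitrogen and Sulfur Deposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing ecological risk to epiphytic macrolichen
    communities from atmospheric nitrogen and sulfur deposition. Builds
    per-site indicator metrics (species richness, sensitive-species
    richness, and functional-group abundance indices) from survey
    detections with ocular abundance codes, fits 90th-percentile quantile
    dose-response curves to deposition with a purpose-built interior-point
    pinball-loss solver, inverts the fitted curves to critical loads and
    20/50/80 percent decline risk classes with pairs-bootstrap confidence
    intervals, derives species-level extirpation-risk thresholds from
    detection-frequency profiles, and compares sensitivity-rating
    distributions among functional groups with analysis-of-means tests.
    Includes a synthetic survey-data generator with a known conditional
    90th-quantile structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
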