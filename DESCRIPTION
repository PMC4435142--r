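Package: odormix
Title: Odor Intensity Prediction for Odorant Mixtures via a Modified Vector Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the perceived odor intensity (OI) of multi-component
    odorant mixtures directly from measured gas-phase concentrations.
    Concentrations are converted to odor activity values (OAV, the ratio of
    concentration to odor threshold); individual-odorant intensity follows the
    log-linear psychophysical law OI = k*lnOAV, and mixture intensity is
    predicted by a modified Vector Model in which all component pairs share a
    single interaction coefficient cos(alpha) derived from the binary-mixture
    counteraction slope beta via cos(alpha) = 2*beta^2 - 1. Includes the
    classic per-pair Vector Model, the Strongest Component Model and an
    intensity-summation baseline for comparison, calibration of (k, cos(alpha))
    from sensory-panel data by regression through the origin, evaluation of
    predictions against panel measurements, a synthetic sensory-panel
    simulator for validation studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
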