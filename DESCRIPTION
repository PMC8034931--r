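Package: actiage
Title: Biological Age Acceleration from Wearable Step-Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates biological age acceleration (BAA) from minute-level
    wearable step counts. Implements raw-accelerometry step counting
    (threshold peak detection, sliding-window de-noising, walking-bout
    filtering), a small one-dimensional convolutional network that maps
    weekly step-count patterns to BAA with Kullback-Leibler
    distribution-alignment losses for device, season and missing-data
    batch effects, Gompertz mortality likelihood fitting with closed-form
    life expectancy, longitudinal resilience analysis via BAA
    autocorrelation times, and the subsampled Mann-Whitney/Fisher group
    comparison procedure. A synthetic-data generator produces circadian
    step series, latent BAA trajectories and survival labels with the
    statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
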