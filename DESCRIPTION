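Package: ptahealth
Title: Tree Health Assessment from Proximity Environmental Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses four-level tree health from seven proximity
    environmental features logged by micro-climate sensors. Provides a
    sequential first-difference three-sigma anomaly screen that masks
    abnormal rows, a from-scratch radial basis function network classifier
    trained by gradient descent with an error-coefficient stopping rule, a
    stratified 10-fold cross-validation harness with confusion matrices,
    feature ablation and a k-nearest-neighbour baseline, and a synthetic
    diurnal sensor-data generator with ground-truth disturbance injection
    for end-to-end testing without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
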