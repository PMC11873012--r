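Package: ratvision
Title: Measuring the Computational Complexity of Rodent Object Vision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis machinery for asking how much
    computational depth a visual object-discrimination task demands,
    built around the comparison of rodent psychophysics with layer-wise
    linear readouts of deep feedforward networks. Includes procedural
    lobed-object stimulus generation with simulated observers, an
    acuity-matched augmentation front end calibrated against a contrast
    sensitivity function via a simulated grating-detection observer,
    untrained VGG-16-layout convolutional and parameter-matched MLP
    architectures with activation extraction, per-layer linear SVM
    readouts with accuracy-pattern comparison metrics, two
    classification-image saliency estimators with permutation
    significance tests, and raw/aligned overlap metrics that dissociate
    screen-centered from object-centered perceptual strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
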