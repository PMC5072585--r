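Package: adaptseg
Title: Feedback Parameter Adaptation for Image Segmentation Pipelines
Version: 0.1.0
Authors@R:
    person("adaptseg", "developers", email = "adaptseg@example.org",
           role = c("aut", "cre"))
Description: Tools for closed-loop tuning of parameterized image segmentation
    pipelines. A feedforward pipeline (mean-filter smoothing, global or Otsu
    intensity thresholding or Sobel edge detection, morphological opening) is
    scored against explicit pixel ground truth via a fuzzy product quality
    criterion, or against abstract user knowledge encoded as trapezoidal fuzzy
    membership functions on object features. Exhaustive grid search then adapts
    the parameter vector per image or robustly over a graded-artifact image
    series. A synthetic benchmark generator produces scenes of solid objects
    degraded by graded shading and Gaussian noise with full pixel ground truth,
    so every experiment is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
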