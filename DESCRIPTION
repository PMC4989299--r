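Package: tendonqus
Title: Quantitative Ultrasound Measurements and Reliability Analysis for
    Tendon Imaging
Version: 0.1.0
Authors@R:
    person("tendonqus", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Extracts quantitative ultrasound (QUS) measurements from
    grayscale B-mode images of tendons within traced regions of interest:
    geometric measurements (thickness, width, cross-sectional area),
    first-order grayscale statistics (echogenicity, variance, skewness,
    kurtosis, entropy) and gray-level co-occurrence texture features
    (contrast, energy, homogeneity).  Quantifies the reliability of each
    measurement with generalizability theory: G-study variance components
    of the fully crossed subject x evaluator x visit x image random model,
    and D-study dependability coefficients, standard error of measurement
    and minimal detectable change for simulated measurement protocols.
    Includes a synthetic speckle-image and feature-table simulator so the
    whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
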