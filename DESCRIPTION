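Package: durianose
Title: Electronic-Nose Signal Processing for Durian Pest and Ripeness Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of low-cost metal-oxide-semiconductor
    (MOS) gas-sensor array measurements for detecting mealybug infestation
    and ripeness stage of durian fruit from volatile emissions. Provides a
    seeded generator of raw per-second sensor streams with realistic drift,
    warm-up transients and temperature/humidity response; acquisition
    utilities that turn streams into windowed-median slope features with
    room-air subtraction; environmental calibration and two-step
    normalization; per-sensor Brunner-Munzel screening; and multivariate
    inference (ANOSIM permutation tests, PCA ripeness trajectories with
    coverage-ellipse stage assignment, linear discriminant classification
    with confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Metabolomics, Classification, Preprocessing
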