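Package: tcmdetect
Title: Detection of Compensatory Movements in Low Back Pain Exercises from
    Spine-Mounted Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates, preprocesses and classifies tri-axial accelerometer
    recordings of low back pain rehabilitation exercises (Prone-Rocking,
    Bird-Dog, Bent-over Rowing) performed either in clinically prescribed
    form (CPE) or with a typical compensatory movement (TCM). Provides a
    synthetic cohort generator emulating three spine-mounted 200 Hz 12-bit
    sensors with a push-button marker channel, marker-based repetition
    segmentation with duration normalization and per-set averaging,
    gravity-projection tilt-angle estimation and statistical feature
    extraction into a z-scored feature matrix, wrapper forward feature
    selection driven by cross-validated decision-tree loss, and a CART
    classifier with Gini impurity and a one-use-per-feature rule, evaluated
    with leave-one-subject-out validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
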