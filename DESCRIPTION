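Package: strokegait
Title: Detection and Classification of Stroke Gaits from Shank Angular
    Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for recognizing hemiplegic stroke gaits from the
    sagittal-plane angular velocity of the shank measured by a wearable
    gyroscope. Segments continuous angular-velocity traces into
    time-normalized gait cycles at mid-swing events, trains a two-part
    multi-label feed-forward neural network (stroke-versus-normal detection
    plus classification of drop foot, circumduction, hip hiking, and back
    knee), and evaluates it under a stratified k-fold cross-validation
    protocol with confusion-matrix metrics. Includes a synthetic gait
    cohort generator with known event locations and abnormality labels,
    readers for a documented IMU CSV dialect and PAMAP2 activity files,
    and packaged confusion-matrix fixtures from a published clinical
    validation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
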