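Package: gojivision
Title: Recognition and Localization of Wolfberry Fruits and Branches from
    RGB-D Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical machine-vision pipelines for wolfberry (goji berry)
    harvesting robots. Fruits are segmented by fusing the a-channel of the
    Lab color space with the I-channel of the YIQ color space through a
    three-level wavelet transform (maximum-absolute-value rule for detail
    coefficients, weighted averaging for the approximation), followed by
    bimodal valley thresholding, morphological opening, connected-component
    area filtering and first-moment centroid localization. Branches are
    segmented by K-means clustering in Lab space with median filtering,
    morphological opening and longest-region selection, yielding a gripping
    point for the robot end effector. Detected pixel coordinates are
    back-projected to 3D camera coordinates with a pinhole model and a depth
    map. A seeded synthetic-orchard scene generator with ground-truth masks
    makes every stage testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
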