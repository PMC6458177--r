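Package: mammodose
Title: Average Glandular Dose Estimation and Model Comparison for Digital
    Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the average glandular dose (AGD) delivered by a
    mammographic exposure with three established formalisms: the Dance
    g-c-s conversion-factor method with population (age and thickness
    based) glandularity, the Wu/Boone entrance-exposure times DgN method
    as implemented by clinical equipment, and the Dance formalism with a
    personalized glandularity measured from the projection image
    (Volpara-style volumetric breast density). Ships the published
    conversion-factor grids, a two-tissue phantom and projection-image
    density estimator, a calibrated synthetic exposure-cohort generator,
    and the comparison analyses (dose ratios stratified by compressed
    breast thickness, density-category distributions, glandularity
    regression on age and thickness, ratio-covariate correlations).
    Reads exposure metadata from CSV or DICOM headers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    pracma,
    optparse
Config/testthat/edition: 3
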