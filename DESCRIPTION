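Package: airtrapcad
Title: Computer-Aided Detection and Severity Scoring of COPD Air Trapping
    from Paired Inspiration-Expiration Lung CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies pulmonary air trapping from paired inspiration and
    expiration thoracic CT volumes.  Lungs are segmented per axial slice
    with a parametric active contour (snake) seeded from air-density
    thresholding; the tracheal air column is tracked to the carina so that
    anatomically corresponding slices can be compared across respiratory
    phases.  Two normalized features - the area variation at the carina
    slice and the total volume variation with slice subsampling - feed a
    two-class univariate Gaussian Bayes classifier (normal vs. COPD
    patient) with closed-form decision thresholds, per-class linear
    severity models, and standard diagnostic accuracy evaluation.  A
    synthetic thoracic phantom generator with analytic ground truth makes
    the whole pipeline testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    MASS,
    RNifti,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
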