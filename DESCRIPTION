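Package: rvdeform
Title: Automatic Classification of Right Ventricular Deformation Patterns
    from Longitudinal Strain Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the four deformation parameters used to stage right
    ventricular (RV) involvement in arrhythmogenic cardiomyopathy from
    speckle-tracking longitudinal strain curves: onset of mechanical
    shortening, peak strain, systolic peak strain, and the post-systolic
    index. Each curve is scored with a points-based rubric and classified
    into deformation pattern type I, II, or III. Includes an automatic
    onset-of-shortening detector based on iterative comparison of local
    strain maxima before pulmonary valve closure, a synthetic strain-curve
    generator with known ground truth for validation, and the agreement
    statistics (Bland-Altman, rank correlation, intraclass correlation,
    time-frame differences) used to compare two sets of annotations.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
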