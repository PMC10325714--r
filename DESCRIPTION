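Package: meibomorph
Title: Meibomian Gland Morphometry and Deformation-Coefficient Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry of meibomian (tarsal) glands from
    infrared-style meibography masks. Generates synthetic eyelid scenes and
    paired two-eye cohorts with known ground-truth gland geometry, provides a
    random image/mask augmentation policy and a classical segmentation
    baseline with evaluation metrics, extracts per-gland boundary and width
    profiles from binary masks, computes an arc-chord-based per-gland
    deformation coefficient, selects and numbers the ten central glands
    (temporal to nasal), and reproduces paired-t / one-way ANOVA / Fisher LSD
    cohort statistics, including recomputation of published summary tables
    from their printed rows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
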