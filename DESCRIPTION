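Package: mimicspec
Title: Avian Visual Modelling and Statistics for Adult Plumage Mimicry Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify visual resemblance between bird specimens
    through the eyes of an avian receiver and to analyse the behavioural
    experiments that test whether the resemblance deceives a host.
    Implements receptor-noise-limited chromatic and achromatic
    discrimination (just-noticeable differences) from cone quantum
    catches, camera-to-cone polynomial mappings for calibrated
    photography, abundant-colour extraction, luminance-histogram and
    Fourier bandpass pattern-energy difference statistics for plumage
    and eggshells, egg volume and shape from outlines, and the
    random-intercept mixed-model and logistic-regression inference
    stages with backward elimination and reference-category rotation.
    A seeded synthetic-data generator emulates museum-skin image sets,
    polymorphic egg clutches and model-presentation trials so the whole
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    withr,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
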