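Package: nirsort
Title: Seed Quality Evaluation and Sorting Metrics from Near-Infrared
    Hyperspectral Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating crop-seed quality (germinability,
    hybridity) from per-seed near-infrared reflectance spectra. Reads
    ENVI-style hyperspectral cubes, calibrates them to absolute
    reflectance, segments seed-occupied pixels and extracts per-seed mean
    spectra; builds the twelve standard chemometric explanatory-variable
    variants (reciprocal / pseudo-absorbance base transforms combined
    with Savitzky-Golay smoothing and standard normal variate
    correction); derives sparse partial least squares discriminant
    models by adaptive-lasso waveband selection and refitting; and
    evaluates sorting performance with precision-recall metrics tailored
    to seed sorting: the standard condition (where seed recovery equals
    the initial eligibility rate and precision equals recall), relative
    precision, the relative-precision-recall curve and its area, and
    unification of scores from several per-trait models. A simulation
    module provides class-conditional normal score models with an
    analytic oracle, plus synthetic spectra and hypercubes with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    signal,
    EBImage,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
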