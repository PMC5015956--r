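Package: phenoplate
Title: Colony-Array Growth Phenomics from Plate Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for solid-medium microbial growth phenomics.
    Converts time series of transmissive grayscale images of pinned colony
    arrays (96, 384 or 1536 format) into calibrated pixel opacities, segments
    colonies against their local background, sums background-subtracted cell
    counts into colony population-size growth curves, and extracts minimum
    population doubling times by sliding-window log-linear regression with
    quality indices. Spatial bias is removed by interpolating a normalization
    surface from a reference grid of isogenic control colonies placed at every
    fourth position; diagnostics quantify residual bias via an adjacency
    false-positive test and coefficient-of-variation summaries. A synthetic
    plate simulator generates ground-truth growth curves and rendered image
    series for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    jsonlite,
    mgcv,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
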