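Package: seedscan
Title: Automated Seed Morphometry from Flatbed Scanner Images
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batch measurement of seed size and shape traits from 8-bit
    grayscale flatbed-scanner images. Computes per-image Otsu thresholds
    pooled into a batch threshold, segments dark seeds from a light
    background, labels 8-connected components, and measures each
    component's area and moment-equivalent ellipse axes. Non-seed
    artifacts (touching seed pairs, scratches, debris) are rejected by an
    ellipse-area consistency test and a major/minor aspect-ratio
    heuristic. Accepted measurements are converted to millimetres,
    aggregated into per-line phenotypes with replicate averaging, and
    characterized by one-way ANOVA variance components and broad-sense
    heritability. A synthetic seed-field generator with per-object ground
    truth makes the whole pipeline testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
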