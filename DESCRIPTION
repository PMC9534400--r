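Package: crownhealth
Title: Tree Crown Health Classification from High-Resolution RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies high-resolution 3-band RGB imagery into four tree crown
    condition classes (green healthy, red dying, gray dead, shadow) with a
    supervised, equation-based partition of HSV color space. Includes the
    exhaustive grid search that calibrates the four model constants against
    labeled training points, accuracy assessment (overall accuracy, Cohen's
    kappa, per-class sensitivity), projection of the pixel model across
    georeferenced rasters with coarse forest masking, extraction of damaged-tree
    objects as polygons and interior points, and a synthetic scene generator for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    grDevices
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
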