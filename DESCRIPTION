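Package: stemspat
Title: Spatial Structure Analysis of Forest Stem Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing marked point patterns arising from fully
    mapped forest plots (stem maps): distance-independent structural indices
    based on the four nearest neighbours (uniform angle, mingling and
    neighbourhood comparison indices), second-order summary statistics
    (univariate and bivariate pair correlation, bivariate Ripley K and
    nearest-neighbour distribution) with translation edge correction,
    the Wiegand two-axis classification of bivariate species association,
    the normalised mark variogram for diameter autocorrelation, Monte Carlo
    simulation envelopes under complete spatial randomness, Thomas cluster
    and random-labelling null models, and a synthetic stem-map generator
    for testing complete analysis pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
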