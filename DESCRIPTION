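Package: larvalsens
Title: Sensitivity Testing for Biophysical Larval-Dispersal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for sensitivity testing of offline Lagrangian
    larval-dispersal simulations. Provides a synthetic depth-stratified
    ocean generator (mesoscale stream-function eddies over idealized
    guyot topography), a passive 2-D particle tracker (fourth-order
    Runge-Kutta advection with bicubic spatial and linear temporal
    interpolation), experiment-design builders for timestep, horizontal
    and vertical release-point separation, release-frequency and
    temporal-range sweeps, and the two analysis engines used to choose
    optimal settings: paired-track Distance Separation over Time (DST)
    against a spatial-autocorrelation threshold, and track-density
    Fraction of Unexplained Variance (FUV) against a model-saturation
    threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
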