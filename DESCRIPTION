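Package: fibrenew
Title: Renewal and Birth-Death Population Dynamics of Phase Singularities
    in Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to model the population dynamics of phase singularities
    (PS) and wavelets in atrial fibrillation as an M/M/infinity birth-death
    process. Provides a preprocessing chain from unipolar electrograms or
    voltage movies to phase maps (QRS subtraction, zero-phase Butterworth
    filtering, sinusoidal recomposition at the dominant frequency, Hilbert
    phase), topological-charge PS detection by convolutional-kernel and
    double-ring methods, zero-phase wavefront extraction, graph-based
    tracking into event tables, exponential renewal-rate estimation of
    formation and destruction rate constants with goodness-of-fit and
    stationarity diagnostics, steady-state M/M/infinity predictions of the
    mean count and count distribution, empirical birth-death transition
    matrices with spectral-gap and mixing-rate analysis, and synthetic-data
    generators (event streams, planted spiral-defect phase movies, a
    two-variable excitable medium, QRS-contaminated electrograms) with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
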