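Package: tactwave
Title: Wavelet Sparsification and Compression of Tactile Sensor-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantization-based sparsification of high-density spatiotemporal
    tactile recordings in 1D, 2D and 3D discrete-wavelet and discrete-cosine
    domains. Provides a registry of orthogonal and biorthogonal wavelet filter
    banks, periodized multilevel transforms with perfect reconstruction, an
    NMSE-targeted binary search for the quantization step, the survey metrics
    (fraction of nonzero coefficients, average bits per pixel, retained energy
    ratio), a survey orchestrator producing ranked tables, diagnostic analyses
    (coefficient-compactness curves, spatiotemporal error profiles,
    grand-average interactions, filter-length trends, scaling-function
    similarity), and a seeded synthetic tactile-grasp generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    signal,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
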