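Package: smflow
Title: Simulation and Analysis of Single-Molecule Flow Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-molecule targeted flow-sequencing experiments,
    in which surface-captured 70-nt DNA templates are extended one reversible
    terminator at a time under a fixed flow order and imaged on a two-channel
    TIRF microscope, and implements the complete image-to-variant analysis
    stack: phase-only correlation drift correction, spot detection with
    Gaussian PSF fitting, photobleaching step counting for single-molecule
    quality control, track-based base calling, Smith-Waterman local alignment
    with a custom scoring scheme, consensus and error-rate profiling, and
    dual-reference detection of low-frequency mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
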