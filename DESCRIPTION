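Package: mgalign
Title: Error-Correction Alignment of Spectrum and Proteoform Mass Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns deconvoluted top-down tandem mass spectra against proteoform
    mass graphs using an error-correction dynamic program. A protein and its
    variable modifications are encoded as a proteoform mass graph (parallel
    unmodified/modified integer-mass edges); a spectrum is encoded as a mass
    graph over discretized prefix masses. Each matched peak receives an integer
    mass correction so that, after correction, the mass between every pair of
    matched peaks equals a theoretical sub-path mass exactly, which bounds the
    accumulated mass error of the whole alignment. Includes fixed and
    peak-dependent tolerance models with dominated-peak pruning and overlap
    deletion, global and banded (diagonal) alignment modes with a C++ core,
    alignment-quality metrics (maximum and average pairwise mass error,
    residue-match histogram), a synthetic proteoform/spectrum simulator with
    ground truth, and file readers/writers plus a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
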