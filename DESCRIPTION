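Package: rbfbarcode
Title: Alignment-Free DNA Barcode Species Identification via Graphical
    Sequence Encodings and RBF Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns DNA barcode sequences (protein-coding COI-like and
    non-coding ITS-like markers) to species without alignment. Sequences are
    encoded as graphical curves - the 2-D Dual-Vector (DV) Curve with its
    24-component S/L characterization, and the 3-D tetrahedral chaos-game
    FJ-Curve with centroid and leading-eigenvalue descriptors of its L/L and
    M/M distance-ratio matrices - and classified by an exact-interpolation
    radial basis function network trained on a reference library. Includes
    the species-level split and k-fold cross-validation protocols, success
    rates with Wilson score confidence intervals, and a synthetic barcode
    simulator with controlled divergence and indels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
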