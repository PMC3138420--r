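Package: aainterp
Title: Descriptor Encoding and Length Normalization of Amino-Acid Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing of variable-length amino-acid sequences for
    machine learning. Sequences are mapped to numeric vectors with one of 532
    bundled physicochemical descriptor scales (531 AAindex scales plus one
    empirical rank scale), optionally rescaled onto [0,1] or [-1,1], and
    normalized to a uniform length with one of five interpolation methods
    (piecewise linear, or cubic splines with Forsythe-Malcolm-Moler, natural,
    or periodic boundary conditions; the spline solvers are implemented from
    first principles with tridiagonal and cyclic-tridiagonal direct solves).
    Includes an AAindex1 flat-file parser, FASTA input, tidy feature-matrix
    output, a synthetic two-class sequence generator, and a cross-validated
    demonstration classifier with rank-based AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
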