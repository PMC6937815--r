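Package: pepmimic
Title: Design of Linear Peptides Mimicking Discontinuous B-Cell Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs linear peptides intended to mimic discontinuous
    (conformational) B-cell epitopes from the three-dimensional structure of a
    protein antigen. Implements 34 design methods over surface-accessible
    segments, spatial clusters and surface patches, including greedy
    nearest-neighbour assembly, distance-optimised orderings, alanine and
    structural-alphabet (protein blocks) linker insertion, and graph-based
    shortest-path and travelling-salesman path methods. Also provides
    crystallographic epitope extraction from antigen-antibody complexes,
    sensitivity/PPV benchmarking of peptide banks in composition and
    position-aware modes, a random-peptide baseline with a closed-form chance
    probability, and a deterministic generator of synthetic test structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
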