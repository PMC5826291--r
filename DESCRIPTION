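Package: nupore
Title: Biomimetic Nuclear Pore Modelling: Coarse-Grained FG-Nup Brushes,
    Density-Based Conductance, and Nanopore Translocation Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling biomimetic nuclear pore complexes built from
    intrinsically disordered FG-nucleoporins grafted inside solid-state
    nanopores. Implements a one-bead-per-amino-acid coarse-grained force field
    with hydrophobicity-scaled attraction and Debye-Hueckel screened
    electrostatics, pore construction with close-packed anchor lattices,
    Langevin dynamics and energy minimization, time-averaged density fields and
    radial profiles, a density-based ionic conductance relation with access
    resistance, umbrella sampling with weighted-histogram free-energy profiles
    and Arrhenius event rates, nanopore current-trace event detection and
    dwell-time statistics, and synthetic-data generators for current traces and
    protein density fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
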