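Package: starphase
Title: Phase Behaviour and Morphometry of Binary DNA Nanostar Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying internal phase separation in binary DNA
    nanostar condensates. Implements the five-species stoichiometry calculus
    for nanostar-linker mixtures (component fractions, sticky-end fractions,
    and the mixing order parameter), a ternary Flory-Huggins free energy
    evolved by conserved Cahn-Hilliard dynamics on a periodic grid, an image
    morphometry pipeline for two-channel condensate micrographs (partition
    coefficients, contact angles, Neumann interfacial-tension ratios, and
    melting-trace breakpoint detection), a combinatorial bond-counting model
    for melting-temperature trends, the linear calibration mapping the
    simulation interaction parameter onto the experimental order parameter,
    and a synthetic-micrograph generator with analytic ground truth for
    validating the measurement pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
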