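Package: repeatspring
Title: Equilibrium Mechanical Ising Analysis of Repeat-Protein Force Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the equilibrium force response of consensus tetratricopeptide
    repeat (CTPR) solenoids in optical-tweezers experiments. Couples a
    helix-resolution nearest-neighbor Ising description of folding energetics to
    worm-like-chain polymer elasticity and the superhelical geometry of the folded
    array to predict force-distance curves, fits those curves to extract intrinsic
    and interfacial stabilities, and derives pathway statistics such as per-helix
    fold-probability profiles, seed sizes, and minimal stable folding units. A
    synthetic-data module emulates instrument output (stretch/relax cycles with
    thermal noise and per-molecule offsets, plus chemical-denaturation curves) so
    the full analysis pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    readr
Suggests:
    testthat (>= 3.0.0),
    arrow,
    withr
Config/testthat/edition: 3
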