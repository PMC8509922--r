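Package: bmpassembly
Title: Kinetic Modeling of BMP Ligand-Receptor Tetramer Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds combinatorial reaction networks for Bone Morphogenetic
    Protein (BMP) ligand dimers binding type I and type II receptors,
    solves the resulting mass-action system to steady state (by a fast
    algebraic equilibrium solver and by ODE integration), and runs
    parameter-space screens for tetramer prevalence, predominance,
    kinase-discounted prevalence, scenario sweeps, and the dynamic-range
    sensor analysis. All user-facing functions take and return tidy data
    frames, with ggplot2 autoplot() methods for each result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
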