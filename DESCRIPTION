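Package: tpskit
Title: Characterisation Toolkit for Terpene Synthase Enzyme Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit for functional and structural
    characterisation of plant terpene synthases. Provides thermofluor
    (differential scanning fluorimetry) melt-curve analysis with Boltzmann
    and derivative melting-temperature estimation and buffer-screen ranking;
    malachite-green phosphate-release kinetics with standard-curve
    calibration and Michaelis-Menten fitting (Km, Vmax, kcat); GC-MS
    peak-table processing into percent-of-total terpene product profiles
    with boiled-enzyme background subtraction and internal-standard
    bookkeeping; and a data-mining-driven crystallisation screen designer
    that parses free-text crystallisation conditions, computes corpus
    frequency statistics and emits a deterministic family-directed sparse
    matrix screen. Seeded synthetic-data generators with recorded ground
    truth make every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
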