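Package: dropscreen
Title: Simulation and Sequencing Analysis of Single-Molecule Droplet Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models droplet-based in vitro screening of degenerate peptide
    libraries: enumeration of NNK-randomised codon libraries, Poisson
    loading of single DNA templates into picoliter drops, in-drop reporter
    fluorescence, threshold-gated drop sorting, RT-PCR amplification bias,
    and short amplicon read simulation. Provides the matching deep
    sequencing analysis: quality trimming, anchor-based extraction of
    randomised codons, translation, per-pool frequency tables and
    fold-enrichment statistics with bootstrap confidence intervals, plus
    a screen-design calculator for library coverage at a chosen loading
    density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
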