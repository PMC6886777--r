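Package: phosphosim
Title: Simulated Phosphopeptide Spectral Libraries for Phosphosite
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates beam-type CID tandem mass spectra of all possible
    singly phosphorylated forms of identified dephosphorylated peptides,
    assembles consensus spectral libraries with shuffle-and-reposition
    decoys, searches phosphopeptide spectra against those libraries with
    binned square-root-intensity dot-product scoring (plus a rank-based
    alternative), and validates phosphorylation-site assignments with
    false-localization-rate (FLR) curves, target-decoy FDR estimation,
    simulation-condition sweeps, and inter-search agreement analysis.
    Includes a synthetic paired phospho/dephospho spectrum generator with
    known ground truth for end-to-end benchmarking.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
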