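Package: swapqc
Title: Quantify, Detect and Remove Barcode Swapping in Multiplexed
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and correcting barcode swapping (index
    hopping) between multiplexed libraries on patterned flow-cell
    sequencers. For plate-based single-cell RNA-seq, estimates the
    swapped-read fraction from impossible barcode combinations by linear
    regression, or from libraries sequenced on two platforms via a pooled
    linear model, with gene-wise swap tests and free-barcode association
    diagnostics. For droplet (10x-style) experiments, tests samples for
    excess cell-barcode sharing with a hypergeometric test, quantifies
    the cost of excluding shared barcodes, and removes individual swapped
    molecules by the majority-read rule. A built-in simulator of the
    swapping mechanism provides ground truth for validation.
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
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vctrs,
    utils
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
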