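Package: pyromux
Title: Multiplex Pyrosequencing Genotyping by Sparse Non-Negative Signal Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for designing and analysing multiplex SNP pyrosequencing
    assays. Simulates theoretical pyrograms from allele sequences and a
    nucleotide dispensation order, builds standardized dictionaries of uniplex
    "atom" signals, searches for dispensation orders that de-correlate atoms,
    decomposes observed multiplex pyro-signals by sparse non-negative
    regression into per-SNP allele contributions with a heterozygote
    correction, and calls bi-allelic genotypes with a confidence index.
    Includes a synthetic signal generator for end-to-end validation and
    comparators for assay turnaround time, reagent cost and waste.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
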