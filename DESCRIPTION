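Package: calculomics
Title: Quantitative Metaproteomics Post-Processing for Dental Calculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of search-engine output for quantitative
    metaproteomics of (ancient) dental calculus: taxonomically stratified
    target-decoy false discovery rate control by score accumulation,
    peptide and protein-group quality-control filtering, lowest-common-
    ancestor taxonomic assignment with a primate-to-human override,
    genus-level label-free quantitation as fractions of bacterial
    intensity, two-group community statistics (t-test volcano,
    Pearson-distance hierarchical clustering, Bray-Curtis dissimilarity),
    and deamidation-aware discrimination of dietary marker peptides via
    in-silico tryptic digestion. Ships a synthetic-data generator with
    known ground truth so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vegan,
    yaml,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
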