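Package: darktaxa
Title: Screening, Primer Design and Niche Statistics for Unidentified
    Soil Fungal Lineages
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for characterising "dark" fungal
    lineages detected as unidentifiable ITS amplicon OTUs in soil
    surveys. The package screens OTUs that match no named reference
    below a similarity threshold, clusters them into candidate
    order-level groups by single-linkage at 80% identity, designs
    taxon-specific PCR primers in the variable ITS region under
    melting-temperature, GC, length, 3'-decamer specificity and
    flank-distance criteria, pairs them with universal eukaryote rRNA
    primers, predicts amplicons in silico, applies overlap-based
    chimera control when assembling long 18S-ITS-28S constructs, and
    quantifies each group's environmental niche (occurrence-weighted
    SD-ratio plus Levene narrowness test with star grading,
    permutation tests for biome/region bias, and repeated k-fold
    cross-validated R2 around a pluggable predictor). A synthetic-data
    module generates annotated rRNA operon families, planted clades,
    chimeras and site-by-OTU occurrence matrices with planted niche
    preferences so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    car,
    mclust,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
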