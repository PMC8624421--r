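Package: enccmosaic
Title: Paired-Tissue Somatic Mosaicism Analysis for Hirschsprung Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cell-type-exclusive somatic variants from paired
    amplicon allele-count tables (enteric neural crest cells versus blood or
    fibroblasts), prioritizes candidates by rarity, deleteriousness and
    enteric-nervous-system expression, compares paired SNP-array profiles for
    mosaic copy-number differences via a B-allele-frequency shift statistic,
    models the sensitivity of threshold-based somatic calling and Sanger
    validation, and simulates rostro-caudal enteric neural crest colonization
    of the gut under neutral, advantageous and disadvantageous selection of a
    mutant clone. Ships synthetic-data generators with known ground truth for
    every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
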