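Package: phagetrait
Title: Discovery of Host-Trait Genes Carried by Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discovering host-trait genes carried
    by bacteriophages, built around the sporulation case: a per-gene
    hypergeometric enrichment test over phages partitioned by the
    spore-forming ability of their predicted hosts, an automated codification
    of scaffold viral-origin curation rules (hallmark-gene context, edge
    rejection, gene-direction switches, non-viral annotation density), and an
    alignment-coverage analysis that detects truncated regulator homologs
    such as effector-only spo0A. A synthetic-data module generates annotation
    tables, host maps, scaffold gene maps and protein alignments with known
    ground truth so the whole pipeline runs end-to-end with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
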