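Package: duoseq
Title: Two-Library Transcriptome Comparison with Chi-Squared Tests and
    Tissue-Enrichment Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for deeply sequenced
    transcriptome libraries without biological replicates, as used for
    insect organ-specific transcript catalogs (for example the mosquito
    spermatheca transcriptome compared between virgin and inseminated
    females). Each coding sequence is tested with a per-CDS 2x2 Pearson
    chi-squared test of mapped-read proportions, with Bonferroni and
    Benjamini-Hochberg control, and ranked by a pseudocounted normalized
    read-rate fold statistic. Includes RPKM/TPM/expression-index
    normalization, z-score matrices with hierarchical clustering for
    heatmaps, tissue-enrichment filtering of organ expression against
    whole-body baseline libraries, keyword-vocabulary functional
    classification, 2^-ddCt relative quantification of qPCR validation
    data, and a negative-binomial count simulator with planted ground
    truth for calibration of error rates and power.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
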