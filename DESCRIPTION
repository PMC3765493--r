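Package: aeikit
Title: Allelic Expression Imbalance Analysis with Mapping-Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring allelic RNA expression ratios at heterozygous
    SNPs from RNA-seq data while attenuating reference-mapping bias. Builds
    IUPAC-masked and allele-switched reference genomes, tallies allelic read
    counts from alignments, folds ratios onto an orientation-free scale,
    combines observations within genes, and calls allelic expression imbalance
    (AEI) under permissive and stringent rules. Also quantifies A-to-I RNA
    editing at catalogued sites with retention filters and cross-condition
    comparisons, and ships a ground-truthed simulator of reference bias so
    every pipeline stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
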