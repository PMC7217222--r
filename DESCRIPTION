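Package: lactgwas
Title: Single-Step GWAS of Lactation-Curve Traits in Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for genetic analysis of milk lactation
    curves. Fits the four-parameter MilkBot model to test-day milk records
    and derives 305-day yield, peak time and peak yield; builds pedigree
    (A), genomic (G) and combined single-step (H) relationship matrices;
    estimates variance components by average-information REML under an
    animal or repeatability model; runs the iterative weighted single-step
    GWAS with 50-SNP window variance decomposition; maps linkage
    disequilibrium blocks over candidate regions; and annotates candidate
    windows with overlapping genes and hypergeometric gene-set enrichment.
    Includes a pedigree/gene-dropping simulator so the whole pipeline is
    testable on synthetic populations with known genetic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
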