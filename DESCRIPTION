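Package: chromdev
Title: Chromatin and Transcriptome Analysis for Fungal Developmental Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of chromatin and transcriptome sequencing data
    from fungal developmental-mutant studies. Provides expression-class-stratified
    fold-change analysis from RNA-seq count tables (RPKM, median-of-ratios size
    factors, MA coordinates, Spearman sample clustering), nucleosome positioning
    from MNase-seq fragments (occupancy tracks, a simplified nucleosome caller
    with peak categories, adjacent-dyad distance histograms, TSS metaplots with
    per-gene maximum normalization, nucleosome-depleted-region metrics), and
    feature-level DNA-methylation quantification from per-cytosine bisulfite
    calls (conversion-rate QC against an unmethylated control contig, the
    at-least-5-percent methylated-cytosine rule, gene-body/upstream/repeat
    aggregation, genotype comparisons). A seeded synthetic-data generator
    emulates the statistical structure of all three assays so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
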