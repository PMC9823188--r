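Package: methylDMR
Title: Windowed Downstream Analysis of Bisulfite-Sequencing Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of post-alignment whole-genome or
    reduced-representation bisulfite sequencing data. Reads per-cytosine
    methylation calls in CGmap format (with converters for Bismark CX
    reports, BSMAP methratio output and METHimpute tables), tiles the
    genome into fixed non-overlapping windows per cytosine context (CG,
    CHG, CHH), and builds window-by-sample methylation matrices under a
    coverage-based eligibility filter. Provides genome-wide and
    gene-centric summaries (PCA, hierarchical clustering of variable
    regions, chromosome-scale tracks, metagene profiles), calls
    differentially methylated regions and genes between two sample groups
    with a choice of two-sample tests, and scores DMR enrichment across
    eight GTF-derived genomic features against the genome background.
    Includes a deterministic synthetic-data generator with known ground
    truth and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ggplot2,
    pheatmap,
    stats,
    utils,
    tools,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
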