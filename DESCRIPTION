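Package: panMethylome
Title: Filtering, Classification and Pangenome-Wide Integration of
    Bacterial Methylation Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of per-site bacterial DNA methylation calls
    (4mC, 5mC, 6mA) produced by nanopore modified-base callers in bedMethyl
    format. Provides validated bedMethyl parsing, coverage and
    methylation-rate filtering with an automatic median-of-medians coverage
    threshold, classification of high-confidence sites against GFF3 or
    GenBank genome annotations into coding and non-coding compartments with
    host and flanking genes, integration of per-genome methylation into
    gene-by-genome matrices over a Roary pangenome, and clustered
    (Hamming-distance, average-linkage) heatmaps of core-gene methylation
    profiles. Includes a synthetic-data generator that emits internally
    consistent bedMethyl, GFF3 and gene_presence_absence inputs with a
    ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
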