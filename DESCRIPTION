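Package: methstage
Title: Stage-Resolved Methylome Analysis for Male Germ-Cell WGBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing of
    developing male germ cells: coverage filtering and symmetric-CpG strand
    merging of cytosine call tables, bisulfite conversion-rate estimation
    from unmethylated lambda spike-ins with nonconversion correction,
    methylation levels at site/window/region resolution in CG and non-CG
    (CH) contexts, segmentation of partially methylated domains with a
    two-state hidden Markov model, stage-specific differentially methylated
    region (DMR) calling with sliding 500-bp windows, Welch tests and
    Benjamini-Hochberg correction, hierarchical clustering of DMR
    methylation trajectories, 5-hydroxymethylcytosine estimation from
    paired bisulfite/oxidative-bisulfite libraries, regulatory-domain
    gene association with expression-change enrichment tests, and a
    synthetic methylome generator with exact planted ground truth for
    validating every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
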