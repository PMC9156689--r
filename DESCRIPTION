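Package: dosagebalance
Title: Dosage-Response Analysis of Small RNA Expression Under Genomic Imbalance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microRNA (and general count-based) expression
    in chromosomal dosage series: partitioning of features into cis and trans
    relative to dosage-varied segments of B-A translocation lines, reads-per-million
    normalization with low-expression filtering and replicate-level quality control,
    a negative-binomial exact test for differential expression with
    Benjamini-Hochberg false discovery rates, classification of per-feature
    dosage responses (gene-dosage effect, inverse dosage effect, dosage
    compensation, increased/decreased/mixed effects) against analytically
    expected fold-change ratios, median trans-ratio trend analysis with exact
    one-dimensional k-means, and Pearson correlation of miRNA expression with
    predicted or degradome-supported target-gene expression. Includes a
    negative-binomial simulator of segmental-aneuploidy and whole-ploidy count
    data with ground-truth response archetypes for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
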