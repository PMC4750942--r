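Package: ferroseq
Title: Iron-Response Endothelial RNA-Seq Analysis with Feature-Level
    Differential Expression and Resampled Enrichment Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-usable pipeline for two-condition, single-library
    strand-specific RNA-seq studies of acute endothelial responses to low
    dose iron: exon/junction read counting with Phred masking and mismatch
    filtering, FPKM normalization, per-gene Welch unequal-variance t-tests
    over exon/junction features with an F-test variance filter, EASE-style
    gene-ontology enrichment with Benjamini-Hochberg and Bonferroni
    adjustment, kappa-based term clustering, and a random-gene-set
    resampling null control. Includes qPCR relative quantification with
    two-reference geometric-mean normalization, sequencing/qPCR concordance
    regression, and proportion/rank/fold-change comparisons for cellular
    damage assays, all driven by a synthetic-data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
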