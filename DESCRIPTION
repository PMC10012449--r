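Package: interewas
Title: Interaction Epigenome-Wide Association Analysis with Reference-Free
    Cell-Composition Adjustment and GWAS Proximity Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) that test
    an exposure-by-phenotype interaction on Illumina-style DNA methylation
    data. Provides probe-level quality-control filters and beta/M-value
    conversion, a reference-free cell-composition adjustment based on
    unsupervised feature selection followed by principal component
    analysis, per-CpG ordinary least squares fits of an interaction model
    with Benjamini-Hochberg false discovery rate control, hypergeometric
    over-representation analysis against gene-set collections,
    a CpG-to-SNP proximity "success ratio" enrichment statistic with
    one-tailed Mann-Whitney group comparisons and per-locus Fisher tests,
    and vicinity-based replication against external association tables.
    A synthetic-data generator with recorded ground truth supports
    end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
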