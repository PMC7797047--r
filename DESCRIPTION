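Package: titraCRISPR
Title: Titratable CRISPRi Library Design and Pooled Fitness Screen Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for titrating gene expression with mismatched CRISPRi
    single guide RNAs and quantifying the growth-rate consequences in pooled
    turbidostat selections. Designs parent sgRNAs against coding sequences
    and expands them into compounding, single and double mismatch series
    plus scrambled negative controls; simulates pooled lineage competition
    with barcoded internal replicates, CRISPRi escaper events and multinomial
    sequencing noise; counts quality-filtered reads into guide-by-barcode-by-
    timepoint tensors; estimates relative growth rates from generation-
    rescaled log-frequency slopes with escaper correction (R-squared filter,
    Dixon Q test, replicate floor); counts statistically resolvable growth
    effects per gene with Welch tests and sequential goodness-of-fit (SGoF)
    correction; and calls gene-by-environment interactions from constrained
    four-parameter logistic titration fits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CRISPR, FunctionalGenomics, PooledScreens, Software
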