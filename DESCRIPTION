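Package: taxenrich
Title: Taxon Set Enrichment Analysis for Microbiome Differential
    Abundance Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rank-based taxon set enrichment analysis for microbial
    communities. Takes per-taxon effect sizes from any differential
    abundance tool (log2 fold changes, correlation coefficients) and
    tests whether predefined sets of taxa (metabolite producers,
    disease signatures, custom groupings) are shifted relative to the
    rest of the community, using a two-sample Kolmogorov-Smirnov test
    with exact small-sample p-values and Benjamini-Hochberg false
    discovery rate control. Includes readers and writers for taxon-set
    databases in GMT and JSON, NCBI taxonomy name-to-taxid resolution
    with an offline cache, a synthetic fixture generator, and a
    signal-implantation benchmark for estimating the true positive
    rate of the enrichment test across set sizes and effect sizes.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
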