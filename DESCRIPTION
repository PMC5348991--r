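Package: spellnet
Title: Database-Guided Construction and Statistical Evaluation of Yeast
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds co-expression networks for yeast microarray experiments by
    combining a differential-expression hit list with per-gene ranked
    co-regulator lists of the kind distributed by the SPELL expression
    compendium. Each hit contributes its top-k co-regulators to a pairwise
    co-occurrence matrix; the matrix yields a weighted network over the hits,
    predicts additional co-regulated "connector" genes from their connection
    counts to the hits, and scores prediction quality with a rank-sum statistic
    (the CoRegScore) calibrated against empirical null distributions from
    random hit lists and permuted expression datasets. Networks are exported in
    Cytoscape-compatible SIF, attribute-table and GraphML formats. A synthetic
    fixture generator with planted co-regulated modules supports fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
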