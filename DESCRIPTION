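Package: cytomem
Title: Stimulus-Induced Epigenomic and Transcriptional Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of innate immune memory in stimulus/washout experiments
    from peak- and gene-level read-count matrices. Calls stimulus-induced
    enhancers and genes with a negative-binomial conditional exact test and
    Benjamini-Hochberg FDR, classifies their persistence after cytokine
    washout under signaling blockade, identifies potentiated and tolerized
    LPS-response genes by contiguous-timepoint fold-change rules, links
    enhancer peaks to candidate target genes by TSS proximity, and scores
    the association between enhancer durability and gene potentiation.
    Includes a negative-binomial synthetic-data generator that plants known
    memory classes so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
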