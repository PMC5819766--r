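Package: sentinelpanel
Title: Sentinel Gene Panel Design and Transcriptome Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid data-driven and knowledge-driven design of sentinel
    (landmark) gene panels from large collections of log2 fold-change
    profiles. Genes are scored for transcriptional diversity (summed
    squared eigengene loadings within k-means experiment clusters) and
    co-expression importance (average squared correlation with
    cluster-mates under 1-|r| hierarchical clustering), combined into an
    overall importance rank, and a fixed-size panel is refined by greedy
    replacement until every canonical pathway is represented by a minimum
    number of genes. A principal-component-regression extrapolation
    matrix predicts the unmeasured transcriptome from the panel, and an
    evaluation suite (Pearson, concordance, significance overlap, MSE,
    fold-change-ranked enrichment scores, cross-validation) quantifies
    how well a panel recreates gene- and pathway-level responses.
    Includes a synthetic fold-change corpus generator with planted
    co-expression modules for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
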