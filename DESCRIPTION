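Package: agemir
Title: Integrative miRNA-mRNA Analysis of Age-Associated Expression in Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies age-associated miRNAs and genes from paired small-RNA
    and mRNA count data and assembles miRNA-mRNA interaction networks. Provides
    a negative-binomial GLM likelihood-ratio test with Cox-Reid common
    dispersion estimation, Fisher's-method meta-analysis of reciprocal
    age-group contrasts with BH FDR control, Pearson correlation integration of
    miRNA and gene expression, direct/indirect target classification against a
    target-prediction table, hypergeometric target-set and pathway
    over-representation analysis, bipartite network export (SIF/GraphML), and a
    negative-binomial count simulator with planted age effects and miRNA-target
    repression couplings for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
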