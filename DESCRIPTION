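Package: phenoplast
Title: Plasticity Phenotypes from Protein Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for constructing and analysing "plasticity phenotypes"
    from replicate western-blot style protein expression tables. Provides
    replicate-run averaging, nearest-neighbour imputation, centred (unscaled)
    principal component analysis with variable diagnostics, heuristic proposal
    and validation of sum and contrast-index plasticity features, colour-coded
    phenotype profiles, tSNE plus k-means clustering with exponential-decay
    elbow selection of k, correlation/dendrogram comparison of subclusters,
    percentile over-representation analysis and bootstrap comparison against a
    reference condition, and a synthetic panel generator with planted ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    rlang,
    Rtsne,
    minpack.lm,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
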