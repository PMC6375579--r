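Package: ratecov
Title: Evolutionary Rate Covariation from Orthogroup Branch Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes evolutionary rate covariation (ERC) between genes from
    per-orthogroup phylogenetic branch lengths on a fixed species topology.
    Branch lengths are normalized against the dataset-average tree by
    through-origin regression; the residuals (relative evolutionary rates,
    RERs) are correlated between gene pairs with Kendall's tau-b on the tree
    pruned to exactly the species the pair shares. Includes focal-gene
    ranking and thresholding, a matrix-representation-with-parsimony (MRP)
    supertree builder, a synthetic-data generator with planted co-functional
    gene modules, and quantification statistics for collective cell-migration
    screens (migration classes, cluster disassociation rates, junctional
    intensity normalization, protrusion-angle sectors, rank-sum contrasts,
    and gene-set over-representation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
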