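Package: cuticlenet
Title: Joint Transcriptome-Metabolome Network Analysis of Plant Cuticle Deposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cuticle-associated gene networks from paired
    transcriptome and cuticle-metabolome profiles of seedling organs. Implements
    weighted gene co-expression network analysis (biweight midcorrelation,
    soft-threshold adjacency, topological overlap, dynamic dendrogram cutting,
    module eigengenes and three-criterion hub-gene calling), random-forest
    association of co-expression clusters with metabolome embeddings,
    permutation-calibrated multivariate gene-to-metabolite importance scoring
    (multi-response PLS, sparse PLS and a randomized-GLM ensemble), network
    integration of the two pipelines, and Fisher-exact functional enrichment.
    Ships a synthetic-data generator that emulates a 6-organ x 4-genotype x
    3-replicate seedling design with planted co-expression modules and planted
    gene-to-metabolite associations, so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
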