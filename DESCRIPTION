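Package: xfcnet
Title: Association-Rule Mining, Efficacy Random Walks and Network
    Pharmacology for Herbal-Formula Treatment of Rheumatoid Arthritis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for evaluating a herbal formula
    (Xinfeng capsule, XFC) in rheumatoid arthritis from routinely collected
    clinical and omics inputs. Codes pre/post laboratory-marker pairs into
    binary improvement transactions and mines treatment-to-improvement
    association rules (support, confidence, lift) with a from-scratch
    level-wise Apriori; models cumulative treatment outcomes as a random
    walk, estimates the scaling exponent of its fluctuation function and
    tests departure from the memoryless null by permutation; screens
    two-group differential expression, intersects differentially expressed
    genes with compound-target lists, selects hub genes by triple-centrality
    intersection and core genes by maximal-clique centrality, screens
    single-gene biomarkers by ROC AUC, and performs local hypergeometric
    over-representation analysis against user-supplied gene sets. A
    synthetic-data module generates every input with configurable, seeded
    statistical structure so the whole pipeline is testable without access
    to the original cohort or microarray accession.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
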