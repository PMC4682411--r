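Package: karmap
Title: Kinase Addiction Ranking and Inhibitor Connectivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deconvolutes kinase dependency from high-throughput drug
    screens. Integrates per-cell-line EC50 drug-sensitivity profiles,
    quantitative kinase-binding panels (Kd, IC50 or percent inhibition)
    and gene expression to score and rank kinases by their association
    with drug sensitivity (sensitivity binning, binding dichotomization,
    expression filtering, point scoring and chi-square/Fisher association
    tests). A companion connectivity-map module matches a query kinase
    set against potency-ranked inhibitor profiles with a
    Kolmogorov-Smirnov enrichment statistic, normalized connectivity
    score and permutation p-value. Includes a seed-deterministic
    synthetic-data generator with planted kinase dependencies for
    end-to-end validation, plus z-scoring and hierarchical-clustering
    reporting of the score matrix.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
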