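Package: threeC
Title: Semi-Unsupervised Subtype Discovery by Categorize, Cluster, Classify
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the three-stage semi-unsupervised "3C" procedure
    (categorize, cluster, classify) for deriving severity subtypes from
    clinical measurements tied to an assigned diagnosis and characterizing
    them with multi-domain objective biomarkers. Provides supervised
    Benjamini-Hochberg screening of clinical measures against an assigned
    diagnosis score, k-medoids (PAM) clustering with Manhattan distance and
    cluster-number selection by the gap statistic and silhouette width,
    cluster characterization by random-forest importance, a CART
    classification tree and marginal one-way ANOVA, a train/validate
    cluster-stability procedure with optimal label matching, bootstrap
    cluster profiles, 5-nearest-neighbour imputation, monotone symmetrizing
    transforms, and a synthetic-cohort generator emulating a 101-subject,
    256-feature multi-domain trauma dataset.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
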