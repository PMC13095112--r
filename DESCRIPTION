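Package: poliscope
Title: Topic-, Region- and Time-Resolved Partisan Polarization from Text
    Embeddings
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures partisan polarization in embedded social-media text
    with a cluster-separation index derived from the C-index: user
    embeddings (mean-pooled tweet vectors) are partitioned by party and the
    sum of within-party pairwise distances is normalized by its attainable
    extremes over the whole population. Includes an exact computation, a
    subsampling approximation with a coefficient-of-variation stopping
    rule, keyword-based party and topic labeling, gazetteer-backed
    geolocation with a two-backend consensus rule, conditioning of the
    index on region, calendar period and topic, event-triggered averaging,
    correlation reporting, and a synthetic-corpus generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    stringi,
    nnet,
    cli
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Clustering, Classification, TimeCourse, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
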