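Package: sandturn
Title: Beta-Diversity Decomposition and Generalized Dissimilarity
    Modelling for Nested Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing species turnover along nested vegetation
    transects: pairwise and multiple-site Sorensen-family dissimilarities
    with their replacement/nestedness decomposition (Baselga) and the
    replacement/richness-difference alternative (Podani-Schmera),
    Whittaker's effective species turnover, turnover-versus-extent
    resampling profiles, generalized dissimilarity modelling with monotone
    I-spline transforms, permutation-based backward elimination and
    three-group deviance partitioning, great-circle geometry and
    convex-hull range sizes, and a synthetic-data generator that emulates
    a nested sandplain survey design for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
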