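Package: coremf
Title: Core Soil Microbiota and Ecosystem Multifunctionality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links soil core microbiota to ecosystem multifunctionality in a
    zoned tree-planting design. Identifies core taxa by a dual
    abundance-occupancy criterion (top decile of mean relative abundance,
    occupancy at least 95% of samples), computes an averaged ecosystem
    multifunctionality index from min-max standardized soil function
    variables, compares communities with Bray-Curtis PCoA and ANOSIM, builds
    a weighted co-occurrence network (soft-thresholded adjacency, topological
    overlap, dynamic branch cutting, module eigengenes, kME-based hub taxa),
    and quantifies drivers of multifunctionality via random-forest permutation
    importance, cluster-abundance regressions, and copiotroph/oligotroph
    composition. Includes a log-normal multinomial community simulator with
    planted ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
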