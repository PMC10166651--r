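Package: microtrace
Title: Individual and Species Assignment from Longitudinal Fecal
    Microbiota Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clustering pipeline for longitudinal compositional
    microbiome profiles that assigns fecal samples to their host species
    and individual. Implements dynamic time warping over per-individual
    time series, shared-nearest-neighbor Jaccard similarity graphs,
    Ward's agglomerative linkage with automatic cluster-number selection,
    greedy modularity community detection, normalized mutual information
    scoring against true labels, and L1-penalized multinomial logistic
    regression to identify the bacterial families that discriminate
    species and individuals. Includes a seeded generator of synthetic
    longitudinal count tables with planted species-, individual- and
    day-level structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
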