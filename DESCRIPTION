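Package: epp
Title: Automated Cytometry Gating by Exhaustive Projection Pursuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, data-driven gating of flow and mass cytometry event
    data by exhaustive projection pursuit. Every qualified pair of marker
    dimensions is examined with a discrete-cosine-transform Gaussian kernel
    density estimate on a 257 x 257 grid; modal clustering partitions each
    density into a planar cluster graph, density-based merging removes
    statistically insignificant separations, and a dual-graph enumeration
    finds every continuous boundary dividing the events into two contiguous
    regions. The best-scoring split is applied recursively until the
    remaining populations admit no statistically supported separation,
    yielding algorithmic phenotypes: a conventional gating tree with
    simplified gate polygons, per-event assignments with Mahalanobis
    distances, and comparison metrics (match tables, Jaccard and central
    similarity). Includes logicle display transforms, a minimal FCS reader,
    and seeded synthetic-data generators for fluorescence-like and
    mass-like event matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
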