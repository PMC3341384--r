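Package: tempomod
Title: Temporal Transcriptional Modules and Regulator Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers maximal temporally coherent transcriptional modules
    (contiguous-column coherent biclusters) from gene expression time series
    using a generalized suffix tree over a discretized transition alphabet,
    scores and filters the modules (pattern p-values with Bonferroni
    correction, cell-based Jaccard overlap, hypergeometric annotation
    enrichment), prioritizes transcription factors for each module at each
    time point by heat-kernel diffusion of expression preference vectors over
    the transposed regulatory network, and renders per-time-point regulatory
    snapshot figures as standalone SVG. Includes a seeded synthetic-data
    generator with planted modules and planted dominant regulators so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    xml2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
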