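Package: fibrasym
Title: Fibration Symmetry and Cluster Synchronization Analysis of Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate structural brain connectivity to functional
    synchronization through graph symmetry. Computes phase-locking value (PLV)
    matrices from region-of-interest time series via the analytic signal,
    detects cluster-synchronization cliques by percolation on the PLV matrix,
    computes minimal balanced colorings (fibers of the symmetry fibration),
    input trees, automorphism groups and orbit partitions of directed
    connectomes, and infers the structural sub-network sustaining an observed
    synchronization pattern by an exact integer edge-edit program (minimal edge
    removals/additions so that a target coloring becomes the balanced coloring
    of the edited graph). Includes seeded generators for phase-locked
    BOLD-like signals, fibration lifts, and admissible synchronous dynamics,
    plus a packaged dorsal-stream language connectome fixture and a pipeline
    reproducing the baseline/rest/task symmetry-breaking analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
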