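Package: critnet
Title: Criticality Analysis of Thresholded Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how information transfer, network topology,
    and connection-weight statistics change as a weighted functional
    connectivity matrix is thresholded. Implements a one-step ternary
    stimulus-response transfer model with a mutual-information readout (plus
    an exact enumeration oracle for small networks), percolation and
    transitivity summaries of the binarized network, maximum-likelihood fits
    of a boundary-power weight-distribution model and of an exponentially
    truncated power law scored by Kolmogorov-Smirnov distance, a synthetic
    small-world connectome generator, and an orchestrated threshold sweep
    that localizes the coincident critical point of these three readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
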