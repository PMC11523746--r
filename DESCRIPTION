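Package: gridness
Title: Detection of Square-Grid Structure in Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects lattice-like (square-grid) arrangements in neuronal
    connectivity networks. Implements a suite of topology metrics
    (transitivity, Lind square clustering, spectral bipartivity, average
    shortest path length and the small-world coefficient sigma with
    degree-preserving random references), parameterized generators for six
    reference network models, a calibration sweep that summarizes metric
    ranges per model, and a two-hop sliding-window scan that classifies
    windows against square-grid criteria, clusters overlapping flagged
    windows and scores each network component for square-grid-ness.
    Connectome edge lists are read from delimited text, and scan results
    are exported as TSV/JSON reports and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
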