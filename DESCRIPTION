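Package: onasurvey
Title: Organizational Network Analysis of Dyadic Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for organizational network analysis (ONA) of
    multi-layer dyadic survey data, as used to map working relationships
    among regional nutrition actors. Reads organization rosters and
    long-format dyadic reports, builds directed valued networks per
    relation layer, applies the mutual-acknowledgement (minimum)
    confirmation rule to obtain symmetric confirmed networks, and
    computes standard sociometric measures: density, Freeman degree and
    betweenness centralization, normalized degree and betweenness
    centrality, isolate detection, and dyad-level multiplexity across
    relation layers. Includes UCINET DL full-matrix input/output, styled
    network plots, and a synthetic survey generator with planted
    homophily, brokers and reporting noise for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    utils,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
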