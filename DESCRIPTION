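Package: hoolinet
Title: Benchmark-Referenced Tests and Signed Networks of Football Fan Violence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for testing transitive friend/enemy ("Bedouin") structure in
    football fan violence from per-match police incident counts. Implements the
    two-step methodology used for the Pernambuco hooligan data: unequal-variance
    mean tests of each club pair against a pooled incident benchmark, defining
    underlying rivalry/alliance relations and coup/peer/clash/split affinities
    with a third club; concordance of inferred relations with declared fan-base
    alliances; construction and export (Pajek, GraphML, CSV) of the signed
    hooligan network with relevance scores and circular layouts; an exhaustive
    oracle that reconstructs minimal integer count vectors from printed summary
    statistics; and an overdispersed count-data simulator with planted relations
    for type-I error and power calibration of the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
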