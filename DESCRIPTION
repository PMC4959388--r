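Package: abclbd
Title: Literature-Based Discovery with Pluggable Word Sense Disambiguation
Version: 0.1.0
Authors@R:
    person("ABCLBD", "Maintainers", email = "maintainers@abclbd.example.org",
           role = c("aut", "cre"))
Description: An implementation of the Swanson A-B-C model of literature-based
    discovery (LBD) driven by concept co-occurrence in publication titles.
    Documents are mapped to concept identifiers (CUIs) through a sense
    inventory, ambiguous terms are resolved by pluggable word sense
    disambiguation (WSD) backends (random, noisy oracle, personalized
    PageRank over a concept graph, and a sense-centroid vector space model),
    a sparse concept co-occurrence matrix is built and squared, and hidden
    knowledge (indirectly but not directly connected concept pairs) is
    extracted and ranked. A time-slicing evaluation protocol scores the
    hidden knowledge against concept pairs that first co-occur after a
    cutoff year, and a synthetic-world generator plants discoverable A-B-C
    triples and ambiguity confounds so the coupling between WSD accuracy
    and LBD performance can be measured end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
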