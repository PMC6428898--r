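Package: rxncycle
Title: Executable Reaction-Contingency Models of the Cell Division Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate and simulate reaction-contingency (rxncon-style)
    knowledge bases of cell-cycle control networks. Parses and writes
    SBtab-compatible model spreadsheets, generates elemental-state skeletons
    from a data-driven reaction-type catalogue, compiles a knowledge base into
    the uniquely defined parameter-free bipartite Boolean model (with delay
    chains implementing timescale separation), simulates it synchronously to
    point or cyclic attractors, classifies mutant genotypes into
    viability/arrest phenotypes against a coarse-grained DNA/spindle-pole-body/
    bud cycle readout, and exports the bipartite regulatory graph for
    Cytoscape-compatible inspection. Includes a random model generator and a
    miniature cell-cycle fixture with a behavioural contract so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
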