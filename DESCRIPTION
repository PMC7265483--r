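Package: antlerphy
Title: Antler Branching Structure, Burr Diagrams, and Ancestral State
    Reconstruction for Cervids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes the branching structure of deer antlers as circular
    burr-projection diagrams built from groove arc-length geometry,
    determines homologous antler elements by comparing diagram signatures,
    codes species-level presence characters from specimen matrices, and
    reconstructs ancestral antler states on a fixed molecular phylogeny
    using Dollo parsimony for presence and Fitch/ACCTRAN refinement for
    within-species frequency grades. Ships a curated element registry,
    species sample table, species-level element-frequency registry and a
    fixed cervid topology, plus simulators for Dollo-consistent character
    histories, binomial specimen sampling and synthetic antler geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
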