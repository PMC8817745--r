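Package: HubScreen
Title: Comparative Hub Analysis and Regulatory Screening of Disease
    Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing protein-protein interaction networks of
    two diseases by degree-centrality hub selection, and for screening the
    shared hub set through directed, typed regulatory action maps
    (expression, activation, inhibition) down to a critical regulator core.
    Reads and writes STRING-style interaction and protein-action edge
    lists, ships a curated liver/pancreatic cancer hub dataset, classifies
    hub regulatory roles, extracts the regulators of the generic central
    node, and generates paired scale-free benchmark networks with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'fixtures.R'
    'network.R'
    'hubs.R'
    'screening.R'
    'synthetic.R'
    'pipeline.R'
    'HubScreen-package.R'
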