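Package: pfnet
Title: Protein Function Prediction from Protein Family Networks and
    InterPro Signature Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multimodal prediction of Gene Ontology annotations for
    proteins. Builds a protein family network linking proteins that share
    InterPro family, domain or motif signatures, runs a two-layer graph
    attention encoder over protein language-model embeddings on that
    network, encodes binary signature profiles with a multilayer
    perceptron, and fuses both towers into a per-term sigmoid classifier
    trained per subontology with neighbourhood sampling, Adam and early
    stopping. Ships a complete CAFA-style evaluation stack (Fmax, Smin
    with information content, AUPRC, per-taxon breakdowns) and a
    synthetic-world generator (ontology, signature catalog, annotations,
    embeddings, splits) so the whole pipeline is testable at desk scale.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
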