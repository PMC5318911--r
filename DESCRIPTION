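Package: rhsac
Title: Rough-Hypercuboid Supervised Attribute Clustering for miRNA-mRNA
    Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised attribute clustering of paired case/control
    expression data using the rough-hypercuboid dependency measure,
    with max-margin rule selection under cross-validation, target-table
    constrained integration of miRNA and mRNA clusters into regulatory
    modules, signed regulatory network expansion, feedforward/feedback
    motif census and expression-contrast condensation, and a kinetic
    model of coherent feedforward-loop repression of p21. Includes a
    synthetic-data generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    deSolve,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
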