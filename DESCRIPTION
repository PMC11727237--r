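Package: gdop
Title: Graph-Convolutional Prediction of Drug On-Target Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the biological pathways a compound acts on ("on-target"
    pathways) from its transcriptional signature and chemical structure. A
    compound's averaged landmark-gene expression profile is propagated over a
    score-filtered protein-protein-interaction graph by a spectral graph
    convolutional encoder, concatenated with a Morgan structural fingerprint,
    and scored against a curated pathway label space by a deep dense network
    trained with masked cross entropy, Adam and early stopping. Includes the
    full curation pipeline (GMT pathway filtering, PPI score thresholding,
    signature averaging, positive labeling from target annotations, 3:1
    negative sampling, train/validation/test splitting), top-N accuracy
    evaluation of ranked predictions, and a seeded planted-signal synthetic
    data generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
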