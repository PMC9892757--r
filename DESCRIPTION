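Package: mdagcan
Title: Microbe-Disease Association Prediction with a Graph Convolutional
    Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts microbe-disease associations from a heterogeneous
    network that fuses known associations with Gaussian interaction profile
    (GIP) kernel similarities and gene-based functional similarities of
    microbes and diseases.  Node embeddings are learned with stacked graph
    convolutional layers followed by a graph attention layer, association
    scores are reconstructed with a bilinear decoder, and training minimises
    a focal loss with the Adam optimiser.  Includes leave-one-out,
    k-fold, and cold-start (disease-row / microbe-column holdout)
    cross-validation protocols, candidate ranking for a query disease, and a
    seeded synthetic-data generator with planted low-rank structure so every
    stage runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
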