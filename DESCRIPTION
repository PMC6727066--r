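Package: lnclink
Title: Graph-Convolutional Auto-Encoder Prediction of lncRNA-miRNA Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised link prediction on bipartite lncRNA-miRNA
    interaction networks. A one-hop spectral graph convolution (renormalized
    adjacency filter) smooths raw expression-profile features over the
    interaction graph; a ReLU encoder projects them to a low-rank latent
    space and a bilinear decoder scores every lncRNA-miRNA pair. Training
    minimises a masked squared loss over the known interactions plus
    negative samples drawn anew each epoch from the unlabeled pairs.
    Includes neighborhood collaborative-filtering, truncated-SVD, Katz-index
    and latent-factor baselines, a repeated k-fold cross-validation harness
    with ranking-based ROC/AUC evaluation, and a synthetic generator that
    plants recoverable low-rank interaction structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
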