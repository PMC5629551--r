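Package: deepsubtype
Title: Unsupervised Deep-Belief-Network Subtyping of Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end unsupervised pipeline for discovering molecular
    subtypes in tumor expression cohorts. Continuous tumor expression is
    discretized to binary aberration calls against Gaussian fits of
    tissue-matched normal controls, calls explained by copy-number
    alteration are masked, and low-information or tissue-confounded genes
    are filtered out. A stack of Bernoulli restricted Boltzmann machines is
    pre-trained by contrastive divergence, unfolded into a deep autoencoder,
    and fine-tuned by cross-entropy backpropagation; top-layer encodings of
    tumors are grouped by subsampled consensus clustering scored with the
    proportion of ambiguous clustering (PAC), with an ensemble
    consensus-of-consensus across independently trained models. Clusters
    are read out clinically via Kaplan-Meier curves with log-rank testing
    and per-cluster ranked gene and mutation correlates. A synthetic cohort
    generator with a planted process-pathway-TF-gene hierarchy makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
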