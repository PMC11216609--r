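Package: topicdrift
Title: Time-Aware Embedded Topic Models for Labeled Document Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits dynamic embedded topic models to time-sliced, labeled
    bag-of-words corpora. Topics live in a word-embedding space and evolve
    across time slices by Gaussian random walks; per-document topic
    proportions are logistic-normal and inferred with an amortized
    variational encoder trained by stochastic gradient descent on the
    evidence lower bound, augmented with a topic-diversity loss and a
    document-label classification loss. Includes a generative simulator
    with recorded latent truth, topic-quality metrics (NPMI, context-window
    and Fitelson coherence, topic diversity, document-completion
    perplexity), and downstream analyses: word-probability trends, cross-
    resolution topic hierarchies, label classification from topic
    proportions, and low-dimensional embedding of documents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    purrr,
    randomForest,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
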