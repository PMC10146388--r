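Package: riskamp
Title: Sentinel Social-Media Surveillance, Topic-Weighted Emotion Scoring,
    and Vector-Autoregressive Analysis of Vaccine Acceptance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-stage infodemiology pipeline linking social-media
    discourse to daily vaccine-acceptance surveys. Stage one selects
    "sentinel" accounts from a weighted directed retweet network by
    directed-modularity (Louvain) community detection, per-community
    retweet rank, and snowball expansion. Stage two fits latent Dirichlet
    allocation by collapsed Gibbs sampling, scores four topic-number
    selection metrics, and computes daily topic-cluster prominence from
    document-topic probabilities. Stage three counts lexicon emotion
    categories per tweet (NRC-style word-category flags), forms net
    sentiment and trust scores, weights them by topic-cluster probability,
    and aggregates to daily series. Stage four tests stationarity with an
    augmented Dickey-Fuller regression, fits bivariate vector
    autoregressions with constant and linear trend, and traces
    orthogonalized impulse-response functions with bootstrap bands,
    including a reverse-causality robustness check. A synthetic-data
    generator with known ground truth (planted communities, topics,
    lexicon tags, and autoregressive coefficients) drives recovery-based
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    withr
Config/testthat/edition: 3
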