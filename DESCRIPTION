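Package: semspike
Title: Single-Neuron Semantic Encoding Analysis for Speech-Aligned Spiking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing semantic encoding by single neurons during
    naturalistic speech: word-embedding handling with spherical k-means
    clustering of words into semantic domains and silhouette-based model
    selection; word-aligned firing-rate matrices; per-neuron semantic
    selectivity statistics (rank-sum tests with Benjamini-Hochberg false
    discovery control, a selectivity index with bootstrap robustness);
    population decoding of semantic domains with linear support vector
    classifiers and permutation nulls; context-dependence analyses (homophone
    contrasts, word-list attenuation, surprisal-conditioned decoding); and a
    neuronal-semantic space built from per-neuron ridge regressions onto word
    embeddings with principal-component and cophenetic-hierarchy analyses.
    Includes a synthetic-data generator that plants semantically tuned Poisson
    spiking populations so the full pipeline runs end to end without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
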