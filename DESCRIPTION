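Package: chunknet
Title: Task-Set Learning by Temporal Chunking in a Two-Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, maximum-likelihood fitting and model-based analysis
    of a two-network model of unsupervised task-set learning. An associative
    network maps stimuli to actions through reward-modulated Hebbian
    plasticity and a soft, noisy winner-take-all rule; a task-set network of
    stimulus-action conjunction populations chunks temporally contiguous
    pairs and, when a reward confirms a retrieved task-set, feeds an
    inference signal back into the associative weights. The package
    generates the recurrent and open-ended experimental sessions (uncued
    task-set switches, misleading feedback), simulates synthetic behavioral
    cohorts, fits the model with and without inference subject by subject
    (grid-seeded bounded optimization, BIC/AIC comparison), and produces the
    model-based trial classifications (chunked versus independent) and
    aligned performance curves used to test the model's behavioral
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
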