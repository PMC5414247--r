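Package: scgdyn
Title: Excitable-Refractory Spike Dynamics and Attractor Embedding on
    Strongly Connected Digraphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the long-run dynamics of excitable-refractory
    spiking units coupled along a strongly connected directed graph with
    per-edge transmission delays.  Provides degree-regular strongly connected
    digraph sampling via an edge-swap Markov chain, an exact event-driven
    simulator of instantaneous spikes with refractory suppression, singular
    spectrum analysis of inter-spike-interval sequences to estimate an upper
    bound on the attractor dimension, K:1 entrainment classification under
    periodic forcing, and a survey harness for measuring how the embedding
    dimension scales with network size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
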