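Package: prismr
Title: Protein Rarity Inference from Stability and Mutational Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the rarity of functional protein sequences in amino
    acid sequence space from mutational-survival curves, tolerated-mutation
    fractions, and stability-change (ddG) distributions. Fits the
    hyper-exponential mutational response P(n) = exp(-alpha*n - beta*n^2),
    locates the sequence-space target region that holds essentially all
    functional sequences, and combines exact combinatorial in-target
    probabilities with per-substitution tolerance to produce upper-bound
    rarity estimates, discovery times for undirected searches, and
    functional-sequence density maps. Includes seeded synthetic-data
    generators so every estimator is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
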