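Package: subseed
Title: Transition-Constrained Subset Seed Design and Adaptive
    Seed-and-Extend DNA Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and using transition-constrained
    (subset) spaced seeds for distant DNA homology search. Computes
    exact hit probabilities of seed sets on Bernoulli alignment models
    by automaton dynamic programming, co-designs multiple seed patterns
    by hill climbing with random restarts, builds per-pattern subset
    suffix arrays supporting adaptive (rareness-thresholded) seeds, and
    performs seed-and-extend local alignment with gapless and gapped
    X-drop extension. Includes a synthetic related-genome-pair
    simulator with configurable identity, transition:transversion
    ratio, indels and repeat masking, plus a chunk-based sensitivity
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
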