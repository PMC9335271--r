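Package: chemspacer
Title: Evolution of the Chemical Space and Convergence of Element Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a growing collection of chemical substances
    shapes similarity relations among chemical elements. Builds year-indexed
    cumulative chemical spaces from substance tables, computes asymmetric
    element substitutability similarities from multisets of arranged formulae,
    derives per-year directed maximum-similarity networks (systems of chemical
    elements), and quantifies their convergence through network overlap,
    backbone extraction and subsampling-based ubiquity. A retrodiction module
    rescales modern molecular formulae to historical atomic-weight systems via
    Farey-sequence rational approximation and scores the resulting networks
    against a reference year. A seeded synthetic chemical-space generator with
    planted element families provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
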