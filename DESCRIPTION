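Package: mfcsim
Title: Simulation and Classical Scoring of Multidimensional Forced-Choice
    Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how much trait information survives the
    translation of Likert-type personality ratings into multidimensional
    forced-choice (MFC) triplet responses.  Generates synthetic Likert
    inventory data from a latent factor model with configurable within-
    and between-scale correlations, builds balanced triplet block designs
    over any number of scales, converts ratings into ranked triplets with
    randomized tie-breaking and binary dummy coding, scores the binary
    responses with classical (+1/-1) forced-choice coding, and evaluates
    how well the forced-choice scores recover the original scale scores
    via cross-correlation matrices, canonical correlation (Pillai trace),
    selection ratios, and item-count learning curves.  Real inventories
    can be ingested from CSV rating and item-metadata files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
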