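Package: indirank
Title: Drug Indication Ranking from Chemical Interactions and Structural Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-label ranking of candidate therapeutic indications for a query
    compound. Candidate indications are scored by the sum of the k largest
    chemical-chemical interaction confidence scores (STITCH
    chemical_chemical.links.detailed dialect) between the query and training
    drugs carrying each indication; when the query has no interaction partner
    the method falls back to the analogous top-k sum of 2D fingerprint Tanimoto
    similarities (ECFP, FCFP, MACCS or path fingerprints). Includes the
    dataset-curation procedures (minimum category size filtering and
    near-duplicate removal by a maximal independent set of the Tanimoto >= 0.7
    graph), jackknife and repeated k-fold order-accuracy evaluation with
    recall/precision at the label-average cutoff, per-category sensitivity, a
    synthetic multi-label fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
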