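Package: herbminer
Title: Improved Apriori Mining of Herbal Prescription Association Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association-rule mining of herb co-prescription patterns with an
    optimized Apriori algorithm: rare-item deletion, a bit-packed Boolean
    incidence matrix with row and column compression, bitwise support
    counting, per-level itemset index tables, and prefix-tree (trie) rule
    generation. Ships naive reference miners for equivalence checking, a
    deterministic synthetic prescription-corpus generator with plantable
    pairwise co-occurrence, contingency-count fixture construction, and
    frequency and rule-table reporting with support, confidence, coverage,
    lift and count metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
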