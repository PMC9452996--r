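---
title: "Mining herb combination rules with an optimized Apriori"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining herb combination rules with an optimized Apriori}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbminer)
```

## The mining model

A prescription corpus is a transaction database: n transactions (one per
prescription), each a duplicate-free set drawn from a vocabulary of m
herbs. For itemsets X, Y with X ∩ Y = ∅, the rule X → Y is scored by
support count(X ∪ Y)/n, confidence count(X ∪ Y)/count(X), coverage
count(X)/n, and lift, the confidence divided by count(Y)/n. Mining
proceeds in the two classic phases — find all itemsets whose support meets
the minimum support, then split each into antecedent/consequent pairs and
keep those meeting the minimum confidence — but the frequent-itemset phase
is reorganized around a bit-packed Boolean incidence matrix:

* **Step 1 (rare-item deletion).** Items whose total occurrence count is
  at most `count_threshold` (default 1) are removed, transactions emptied
  by the removal are dropped, and the pass repeats to a fixed point,
  since dropping a transaction can push another item under the threshold.
  An item below the absolute support threshold can never occur in a
  frequent itemset, so the surviving frequent itemsets are identical;
  what *does* change is the denominator: supports are fractions of the
  transaction count that enters the matrix. This is deliberate — it is
  how a corpus of 242 raw prescriptions can be mined over an effective
  grid of 238 transactions, and the package treats n as a property of the
  data actually mined, never a constant.
* **Step 2 (Boolean matrix).** Bit (i, j) is 1 iff herb i belongs to
  prescription j. An itemset's support is the popcount of the AND of its
  rows, restricted to the live-column mask. Two compressions narrow the
  masks as levels advance: rows of items that appear in no frequent
  itemset at the current level (supersets of infrequent sets are
  infrequent), and columns of transactions with fewer live items than the
  current level k (a short transaction cannot contain a k-itemset).
  Both are sound: the test suite checks that toggling either compression
  never changes a single itemset, count or rule.
* **Step 3 (index tables).** Each level k maps every canonically ordered
  frequent k-itemset to its support count. Candidates for level k + 1
  join two level-k itemsets sharing a (k−1)-prefix and are pruned by
  downward closure before any counting. Level-1 supports come from the
  vocabulary counts collected while reading the data, so the database is
  scanned only to build the vocabulary and once more to build the matrix.
* **Step 4 (trie rule generation).** Frequent itemsets are inserted into
  a prefix tree keyed by canonical item order. For every frequent Z with
  |Z| ≥ 2 and every non-empty proper subset X, the rule X → Z∖X is scored
  by two trie lookups; multi-item antecedents and consequents are both
  allowed, and `max_rhs = 1` reproduces the single-consequent view used
  in published rule tables.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `min_support` | minimum fraction of transactions containing a rule's items | 0.13 | the study setting for the prescription corpus |
| `min_confidence` | minimum P(consequent \| antecedent) | 0.60 | the study setting |
| `count_threshold` | Step-1 deletion bound on item occurrence counts | 1 | the literal "seen once" reading; any value below the absolute support threshold is sound, and 0 disables Step 1 |
| `max_k` | largest itemset size | unlimited | mining stops naturally when a level is empty |
| `max_rhs` | cap on consequent size | none | published tables show single consequents; the rule space itself is unrestricted |

Thresholds are inclusive: an itemset is frequent iff its count is at
least ⌈min_support · n⌉ (at 13% of 238 that is 31). The ceiling is
computed with a 1e-9 fuzz because binary floats can push an exact product
just over the next integer (0.3 × 30 evaluates above 9 in doubles); the
fuzz is far below any attainable support granularity of 1/n.

## Canonical order and determinism

Item order is byte-lexicographic by label (radix sort, locale
independent). Every itemset is stored and printed in that order, trie
paths follow it, and rules sort by support then confidence (descending),
then antecedent and consequent labels — so a corpus mines to
byte-identical output on any platform.

## The synthetic corpus generator

Real prescription corpora are not always shareable, so
`generate_corpus()` draws one with the statistical shape that matters for
this algorithm: 238 transactions over 237 herbs, transaction sizes
uniform on 5–20, and a power-law popularity profile `(1:m)^-0.55`
calibrated so the most popular herb lands in roughly 40% of transactions
— the dominance a core herb like Gancao shows in real treatment plans.
Planted pairs are injected into disjoint transaction sets before
background sampling, and the planted herbs are excluded from the
background pool, so realized joint counts are exact by construction (and
re-verified by recount before the corpus is returned). The generator is
seeded and bit-reproducible.

What it does **not** emulate: pharmacological structure (herbs are
exchangeable apart from popularity), dosage, syndrome-specific
sub-corpora, or higher-order planted correlations. Passing tests on these
corpora therefore demonstrate algorithmic correctness — equivalence with
the naive miners, compression soundness, metric identities — not clinical
validity of any mined rule.

`build_contingency_fixture()` is the complementary generator: given one
rule's contingency counts (n, count(X), count(Y), joint count) it
constructs a database realizing them exactly, padding the remainder with
filler herbs. The default "paired" filler scheme gives every filler a
count of 2 (two fillers per remainder transaction, ring-paired) so Step-1
deletion at the default threshold removes nothing and the denominator
stays at n; the "singleton" variant gives fillers count 1 so Step 1
demonstrably removes them and shrinks the denominator. A remainder of
exactly 1 cannot be ring-paired without collapsing a duplicate pair, so
the paired variant rejects it.

## Numerical and design choices

* Supports are ratios of integer counts; metrics are materialized as
  floats only at output, and the identities confidence · coverage =
  support and lift · P(consequent) = confidence are checked in
  cross-multiplied integer form in the tests.
* Reference miners are intentionally naive. The exhaustive enumerator
  checks every non-empty subset of the vocabulary (refused above m = 20)
  against every transaction; textbook Apriori counts with plain set
  membership and generates rules with direct recounts. Equivalence suites
  compare all three miners on randomized corpora with the Step-1 deletion
  disabled, because the textbook algorithm has no such step and a dropped
  transaction would change every denominator; Step 1's own guarantees
  (fixed point, idempotence, invariance of frequent itemsets) are tested
  separately.
* Degenerate inputs: empty databases, all-zero incidence rows and blank
  basket lines are rejected or dropped with a warning; a database whose
  items are all rare fails with "empty database after pruning"; an empty
  frequent-itemset table generates an empty rule set, not an error.
* Problem sizes in the test suite: randomized equivalence runs use
  corpora of up to 40 transactions over up to 12 items — large enough
  that every code path (multi-level joins, both compressions, multi-item
  antecedents) is exercised, small enough that the exhaustive enumerator
  stays an honest oracle; 200+ corpus/parameter combinations run in
  well under a minute.

## Limitations

* No FP-growth; the optimized pipeline is compared against classic
  Apriori and exhaustive enumeration only.
* No redundant-rule pruning or significance testing; every strong rule is
  reported.
* Runtime claims are not part of the contract — the suite verifies output
  equivalence, not speed-ups, since timings are hardware-bound.
* Support denominators follow the mined database (post Step-1); corpora
  whose Step-1 pass drops transactions will report supports on the
  reduced n, which is the intended behaviour but worth remembering when
  comparing against tools that never drop transactions.
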