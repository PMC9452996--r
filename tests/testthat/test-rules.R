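test_that("trie stores every frequent itemset with its exact count", {
  tab <- mine_frequent(toy_db(), mining_params(0.5, 0.6, 1L))
  trie <- build_trie(tab)
  ids <- function(labs) match(labs, tab$labels)
  expect_equal(trie_lookup(trie, ids("A")), 3L)
  expect_equal(trie_lookup(trie, ids("B")), 3L)
  expect_equal(trie_lookup(trie, ids(c("A", "B"))), 2L)
  expect_equal(trie_lookup(trie, rev(ids(c("A", "B")))), 2L)
  # absent itemsets read as not frequent
  expect_true(is.na(trie_lookup(trie, 999L)))

  empty <- mine_frequent(transaction_db(list("A", "B")),
                         mining_params(1.0, 0.6, 0L))
  trie0 <- build_trie(empty)
  expect_true(is.na(trie_lookup(trie0, 1L)))
})

test_that("trie lookups agree with the flat index table on random corpora", {
  for (seed in 1:8) {
    db <- random_db(seed)
    tab <- mine_frequent(db, mining_params(0.1, 0.6, 0L))
    trie <- build_trie(tab)
    for (k in seq_along(tab$levels)) {
      for (key in names(tab$levels[[k]])) {
        ids <- herbminer:::key_to_ids(key)
        expect_equal(trie_lookup(trie, ids), tab$levels[[k]][[key]])
        expect_equal(trie_lookup(trie, rev(ids)), tab$levels[[k]][[key]])
      }
    }
    set.seed(seed + 1000)
    for (rep in 1:100) {
      ids <- sample(db$m, sample(1:min(4, db$m), 1))
      expect_equal(trie_lookup(trie, ids),
                   herbminer:::table_lookup(tab, ids))
    }
  }
})

test_that("rule metrics reproduce the published contingency arithmetic", {
  m <- rule_metrics(36, 49, 69, 238)
  expect_equal(unname(m), c(36 / 238, 36 / 49, 49 / 238,
                            (36 / 49) / (69 / 238)))
  expect_equal(signif(m[["support"]], 7), 0.1512605)
  expect_equal(signif(m[["confidence"]], 7), 0.7346939)
  expect_equal(signif(m[["coverage"]], 7), 0.2058824)
  expect_equal(signif(m[["lift"]], 7), 2.534161)

  # perfect implication: confidence 1, lift n/c
  m2 <- rule_metrics(5, 5, 5, 20)
  expect_equal(m2[["confidence"]], 1)
  expect_equal(m2[["lift"]], 4)

  expect_equal(signif(rule_metrics(22, 26, 93, 238)[["lift"]], 7), 2.165426)
  expect_error(rule_metrics(6, 5, 5, 10), "invalid contingency")
})

test_that("rule generation emits all strong antecedent/consequent splits", {
  tab <- mine_frequent(toy_db(), mining_params(0.5, 0.6, 1L))
  rules <- generate_rules(tab, min_confidence = 0.6)
  expect_equal(nrow(rules), 2L)
  expect_equal(rules$lhs, c("A", "B"))
  expect_equal(rules$rhs, c("B", "A"))
  expect_equal(rules$support, c(0.5, 0.5))
  expect_equal(rules$confidence, rep(2 / 3, 2))
  expect_equal(rules$coverage, c(0.75, 0.75))
  expect_equal(rules$lift, rep(8 / 9, 2))

  expect_equal(nrow(generate_rules(tab, min_confidence = 1.0)), 0L)
})

test_that("raising thresholds shrinks the rule set (subset relation)", {
  for (seed in 1:20) {
    db <- random_db(seed)
    key <- function(r) paste(r$lhs, r$rhs, sep = "=>")
    lo <- herb_apriori(db, 0.1, 0.5, count_threshold = 0L)
    hi_s <- herb_apriori(db, 0.3, 0.5, count_threshold = 0L)
    hi_c <- herb_apriori(db, 0.1, 0.8, count_threshold = 0L)
    expect_true(all(key(hi_s$rules) %in% key(lo$rules)))
    expect_true(all(key(hi_c$rules) %in% key(lo$rules)))
    expect_metric_identities(lo$rules, lo$n_total)
  }
})

test_that("lift is symmetric between a rule and its reverse", {
  for (seed in 1:10) {
    db <- random_db(seed)
    rules <- herb_apriori(db, 0.1, 0.2, count_threshold = 0L)$rules
    if (nrow(rules) == 0L) next
    key <- paste(rules$lhs, rules$rhs, sep = "=>")
    rev_key <- paste(rules$rhs, rules$lhs, sep = "=>")
    hit <- match(rev_key, key)
    found <- !is.na(hit)
    expect_true(any(found))
    expect_equal(rules$lift[found], rules$lift[hit[found]])
  }
})

test_that("a consequent-size cap reproduces the single-consequent view", {
  db <- random_db(3, n = 40, m = 8)
  all_rules <- herb_apriori(db, 0.1, 0.5, count_threshold = 0L)$rules
  capped <- herb_apriori(db, 0.1, 0.5, count_threshold = 0L,
                         max_rhs = 1L)$rules
  single <- all_rules[!grepl("+", all_rules$rhs, fixed = TRUE), ]
  rownames(single) <- NULL
  expect_identical(rules_core(capped), rules_core(single))
})
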