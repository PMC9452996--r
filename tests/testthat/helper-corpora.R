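# Small random databases for property suites, plus comparison helpers.

# skewed random DB: n transactions over m single-letter items, transaction
# sizes 2..5 (>= 2 keeps rare-item deletion from emptying transactions in
# the suites that exercise it)
random_db <- function(seed, n = NULL, m = NULL, min_size = 2L, max_size = 5L) {
  set.seed(seed)
  if (is.null(n)) n <- sample(8:40, 1L)
  if (is.null(m)) m <- sample(5:12, 1L)
  w <- seq_len(m)^(-0.7)
  labels <- LETTERS[seq_len(m)]
  txns <- lapply(seq_len(n), function(j) {
    s <- sample(min_size:min(max_size, m), 1L)
    labels[sample.int(m, s, prob = w)]
  })
  transaction_db(txns)
}

# index tables equal: same levels, same canonical itemsets, same counts
expect_same_table <- function(a, b) {
  expect_equal(length(a$levels), length(b$levels))
  expect_identical(a$labels, b$labels)
  for (k in seq_along(a$levels))
    expect_identical(a$levels[[k]], b$levels[[k]])
  expect_identical(a$n_total, b$n_total)
}

rules_core <- function(r)
  as.data.frame(r)[c("lhs", "rhs", "count", "lhs_count", "rhs_count")]

expect_same_rules <- function(a, b, tol = 1e-12) {
  expect_identical(rules_core(a), rules_core(b))
  for (col in c("support", "confidence", "coverage", "lift"))
    expect_equal(a[[col]], b[[col]], tolerance = tol)
}

# exact metric identities on the integer counts carried by a rule table
expect_metric_identities <- function(rules, n_total) {
  if (nrow(rules) == 0L) return(invisible())
  expect_identical(rules$support, rules$count / n_total)
  expect_identical(rules$confidence, rules$count / rules$lhs_count)
  expect_identical(rules$coverage, rules$lhs_count / n_total)
  expect_identical(rules$lift,
                   (rules$count / rules$lhs_count) /
                     (rules$rhs_count / n_total))
  # confidence * coverage = support and lift * P(rhs) = confidence
  expect_equal(rules$confidence * rules$coverage, rules$support,
               tolerance = 1e-15)
  expect_equal(rules$lift * (rules$rhs_count / n_total), rules$confidence,
               tolerance = 1e-15)
}

toy_db <- function() {
  transaction_db(list(c("A", "B"), c("A", "B"), "A", c("B", "C")))
}
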