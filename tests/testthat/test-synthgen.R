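test_that("corpus generation is bit-reproducible and respects its spec", {
  a <- generate_corpus(n_transactions = 238, n_items = 237, seed = 7)
  b <- generate_corpus(n_transactions = 238, n_items = 237, seed = 7)
  expect_identical(a, b)
  expect_equal(a$n, 238L)
  expect_lte(a$m, 237L)
  sizes <- lengths(a$transactions)
  expect_true(all(sizes >= 5L & sizes <= 20L))
  # different seeds give different corpora
  expect_false(identical(a, generate_corpus(seed = 8)))
})

test_that("planted pairs realize their joint counts exactly", {
  db <- generate_corpus(seed = 11, planted_pairs = list(
    list("Shengshigao", "Xingren", 36), list("Gancao", "Chenpi", 22)))
  mat <- build_matrix(db)
  ids <- function(labs) match(labs, db$labels)
  expect_equal(support_count(mat, ids(c("Shengshigao", "Xingren"))), 36L)
  expect_equal(support_count(mat, ids(c("Chenpi", "Gancao"))), 22L)
  expect_error(generate_corpus(seed = 1, planted_pairs = list(
    list("NoSuchHerb", "Gancao", 5))), "unknown item")

  expect_error(generate_corpus(n_transactions = 10, seed = 1,
                               planted_pairs = list(list(1, 2, 11))),
               "exceeds")
})

test_that("item marginals follow the popularity weights", {
  # tiny enumeration oracle: inclusion probability of each item when two
  # items are drawn without replacement with weights w
  incl_prob <- function(w) {
    m <- length(w); p <- w / sum(w)
    out <- numeric(m)
    for (i in 1:m) {
      pr <- p[i]  # drawn first
      for (j in setdiff(1:m, i))  # drawn second after j
        pr <- pr + p[j] * p[i] / (1 - p[j])
      out[i] <- pr
    }
    out
  }
  w <- c(5, 3, 1, 1, 1)
  p <- incl_prob(w)
  n_txn <- 40L
  counts <- numeric(5)
  for (s in 1:100) {
    db <- generate_corpus(n_transactions = n_txn, n_items = 5,
                          item_freq_weights = w, txn_size_range = c(2, 2),
                          seed = s, labels = paste0("It", 1:5))
    counts <- counts + item_counts(db)[paste0("It", 1:5)]
  }
  trials <- 100L * n_txn
  for (i in 1:5) {
    mu <- trials * p[i]
    sd3 <- 3 * sqrt(trials * p[i] * (1 - p[i]))
    expect_gt(counts[i], mu - sd3)
    expect_lt(counts[i], mu + sd3)
  }

  # at corpus scale the default skew puts the top-weight item on top
  db <- generate_corpus(seed = 5)
  expect_equal(frequency_report(db, 1)$item, "Gancao")
  expect_gt(frequency_report(db, 1)$fraction, 0.3)
  expect_lt(frequency_report(db, 1)$fraction, 0.5)
})

test_that("contingency fixtures realize their counts exactly", {
  db <- build_contingency_fixture(238, 49, 69, 36, "Shengshigao", "Xingren")
  expect_equal(db$n, 238L)
  mat <- build_matrix(db)
  ids <- function(labs) match(labs, db$labels)
  expect_equal(support_count(mat, ids("Shengshigao")), 49L)
  expect_equal(support_count(mat, ids("Xingren")), 69L)
  expect_equal(support_count(mat, ids(c("Shengshigao", "Xingren"))), 36L)

  toy <- build_contingency_fixture(4, 3, 3, 2, "A", "B")
  expect_equal(toy$n, 4L)

  expect_error(build_contingency_fixture(10, 5, 5, 6, "A", "B"),
               "infeasible")
  expect_error(build_contingency_fixture(100, 99, 98, 98, "A", "B"),
               "remainder")
})

test_that("paired fillers survive Step 1 with n intact; singleton fillers shrink it", {
  paired <- build_contingency_fixture(50, 10, 12, 8, "L", "R",
                                      filler = "paired")
  pr <- prune_rare_items(paired, 1L)
  expect_equal(pr$n, 50L)  # count-2 fillers survive

  single <- build_contingency_fixture(50, 10, 12, 8, "L", "R",
                                      filler = "singleton")
  ps <- prune_rare_items(single, 1L)
  expect_equal(ps$n, 10L + 12L - 8L)  # filler-only transactions dropped
  expect_equal(ps$labels, c("L", "R"))
})
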