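# Deterministic generators for prescription-like corpora. Two flavours:
# generate_corpus() draws a random corpus with a skewed item-popularity
# profile and optional planted pairwise co-occurrences (exact joint
# counts); build_contingency_fixture() constructs a database realizing one
# rule's contingency table exactly, for metric reconstruction.

#' Default herb label set
#'
#' The twenty high-frequency herb names of the prescription corpus followed
#' by synthetic `HerbNNN` labels, giving a vocabulary of any requested size.
#'
#' @param m Number of labels.
#' @return Character vector of `m` unique labels.
#' @export
herb_labels <- function(m) {
  top20 <- c("Gancao", "Huoxiang", "Xingren", "Fuling", "Chenpi", "Lianqiao",
             "Maidong", "Shengshigao", "Jinyinhua", "Huangqi", "Cangzhu",
             "Houpu", "Jiegeng", "Chaobaizhu", "Shenghuangqi", "Yiyiren",
             "Fangfeng", "Lugen", "Fabanxia", "Chaihu")
  if (m <= 20L) return(top20[seq_len(m)])
  c(top20, sprintf("Herb%03d", seq_len(m - 20L)))
}

#' Generate a synthetic prescription corpus
#'
#' Draws `n_transactions` herb sets. Each transaction's size is uniform on
#' `txn_size_range`; items are sampled without replacement with
#' probabilities proportional to `item_freq_weights`, so popular herbs
#' recur across prescriptions the way a handful of core herbs dominate real
#' treatment plans. Defaults emulate the study corpus: 238 prescriptions,
#' 237 herbs, 5-20 herbs each, and a power-law popularity profile whose top
#' item lands in roughly 40% of transactions.
#'
#' Planted pairs are injected first: for each `(a, b, count)` triple,
#' exactly `count` transactions receive both items, and neither item is
#' ever drawn by the background sampler, so the realized joint count is
#' exact by construction (verified before return).
#'
#' @param n_transactions,n_items Corpus dimensions.
#' @param item_freq_weights Positive popularity weights, recycled/validated
#'   to length `n_items`. Default `(1:n_items)^-0.55`.
#' @param txn_size_range Length-2 integer vector, inclusive bounds on herbs
#'   per prescription.
#' @param planted_pairs Optional list of `list(a, b, count)` triples; `a`,
#'   `b` are labels or indices into the vocabulary.
#' @param seed Integer seed; the corpus is bit-reproducible given the seed.
#' @param labels Vocabulary labels, default [herb_labels()].
#' @return A [transaction_db()].
#' @export
generate_corpus <- function(n_transactions = 238L, n_items = 237L,
                            item_freq_weights = NULL,
                            txn_size_range = c(5L, 20L),
                            planted_pairs = list(), seed = 1L,
                            labels = herb_labels(n_items)) {
  stopifnot(n_transactions >= 1L, n_items >= 1L,
            length(labels) == n_items, !anyDuplicated(labels))
  if (is.null(item_freq_weights))
    item_freq_weights <- seq_len(n_items)^(-0.55)
  stopifnot(length(item_freq_weights) == n_items, all(item_freq_weights > 0))
  txn_size_range <- as.integer(txn_size_range)
  stopifnot(length(txn_size_range) == 2L, txn_size_range[1L] >= 1L,
            txn_size_range[1L] <= txn_size_range[2L],
            txn_size_range[2L] <= n_items)

  as_idx <- function(x) {
    if (is.character(x)) x <- match(x, labels)
    x <- as.integer(x)
    if (is.na(x) || x < 1L || x > n_items)
      stop("planted pair names an unknown item", call. = FALSE)
    x
  }
  planted_pairs <- lapply(planted_pairs, function(p)
    list(a = as_idx(p[[1L]]), b = as_idx(p[[2L]]), count = as.integer(p[[3L]])))
  if (any(vapply(planted_pairs, function(p) p$count, 0L) > n_transactions))
    stop("planted joint count exceeds the transaction count", call. = FALSE)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  planted_items <- unique(unlist(lapply(planted_pairs, function(p) c(p$a, p$b))))
  background <- setdiff(seq_len(n_items), planted_items)
  if (length(background) == 0L)
    stop("no background items left after planting", call. = FALSE)

  # assign injection slots; pairs draw disjoint transaction sets so each
  # realized joint count is exact even when pairs share an item
  free <- seq_len(n_transactions)
  inject <- vector("list", n_transactions)
  for (p in planted_pairs) {
    if (length(free) < p$count)
      stop("infeasible planted counts: not enough transactions left",
           call. = FALSE)
    pickpos <- sample(length(free), p$count)
    for (j in free[pickpos])
      inject[[j]] <- c(inject[[j]], p$a, p$b)
    free <- free[-pickpos]
  }

  w <- item_freq_weights[background]
  txns <- vector("list", n_transactions)
  size_pool <- seq.int(txn_size_range[1L], txn_size_range[2L])
  sizes <- if (length(size_pool) == 1L) rep.int(size_pool, n_transactions)
           else sample(size_pool, n_transactions, replace = TRUE)
  for (j in seq_len(n_transactions)) {
    fixed <- unique(inject[[j]])
    nbg <- max(0L, sizes[j] - length(fixed))
    nbg <- min(nbg, length(background))
    bg <- if (nbg > 0L) background[sample.int(length(background), nbg,
                                              prob = w)] else integer()
    ids <- sort(unique(c(fixed, bg)))
    if (length(ids) == 0L) ids <- background[sample.int(length(background), 1L,
                                                        prob = w)]
    txns[[j]] <- ids
  }

  db <- new_transaction_db(sort(labels, method = "radix"),
                           lapply(txns, function(ids)
                             sort(match(labels[ids],
                                        sort(labels, method = "radix")))))
  # verify planted joint counts by direct recount
  for (p in planted_pairs) {
    pair <- sort(match(labels[c(p$a, p$b)], db$labels))
    got <- sum(vapply(db$transactions, function(t) all(pair %in% t),
                      logical(1)))
    if (got != p$count)
      stop("internal error: planted pair realized count ", got,
           " != target ", p$count, call. = FALSE)
  }
  db
}

#' Build a database realizing one rule's contingency counts exactly
#'
#' Constructs `n` transactions: `c_joint` containing both `lhs_label` and
#' `rhs_label`, `c_lhs - c_joint` containing only the antecedent,
#' `c_rhs - c_joint` containing only the consequent, and the remainder
#' containing filler herbs only. With `filler = "paired"` (default) each
#' remainder transaction holds two filler herbs and every filler occurs in
#' exactly two transactions, so rare-item deletion at threshold 1 leaves
#' the transaction count at `n`; with `filler = "singleton"` each remainder
#' transaction holds one unique filler (count 1), exercising the path where
#' Step 1 removes the filler, drops the emptied transaction and shrinks the
#' mining denominator.
#'
#' All realized counts are re-verified by direct recount before return.
#'
#' @param n Total transaction count.
#' @param c_lhs,c_rhs,c_joint Marginal and joint occurrence counts;
#'   `c_joint <= min(c_lhs, c_rhs)` and the union must fit in `n`.
#' @param lhs_label,rhs_label Item labels.
#' @param filler `"paired"` or `"singleton"` (see above).
#' @return A [transaction_db()].
#' @examples
#' db <- build_contingency_fixture(238, 49, 69, 36, "Shengshigao", "Xingren")
#' db$n
#' @export
build_contingency_fixture <- function(n, c_lhs, c_rhs, c_joint,
                                      lhs_label = "LHS", rhs_label = "RHS",
                                      filler = c("paired", "singleton")) {
  filler <- match.arg(filler)
  n <- as.integer(n); c_lhs <- as.integer(c_lhs)
  c_rhs <- as.integer(c_rhs); c_joint <- as.integer(c_joint)
  if (!(c_joint >= 0L && c_joint <= min(c_lhs, c_rhs)))
    stop("infeasible counts: joint exceeds a marginal", call. = FALSE)
  if (c_lhs + c_rhs - c_joint > n)
    stop("infeasible counts: union exceeds n", call. = FALSE)
  if (lhs_label == rhs_label) stop("labels must differ", call. = FALSE)
  rest <- n - (c_lhs + c_rhs - c_joint)
  if (filler == "paired" && rest == 1L)
    stop("paired fillers need the remainder to be 0 or >= 2", call. = FALSE)
  txns <- c(
    replicate(c_joint, c(lhs_label, rhs_label), simplify = FALSE),
    replicate(c_lhs - c_joint, lhs_label, simplify = FALSE),
    replicate(c_rhs - c_joint, rhs_label, simplify = FALSE)
  )
  if (rest > 0L) {
    if (filler == "paired") {
      # ring pairing: transaction j holds fillers F_j and F_{j+1 (mod rest)},
      # so every filler occurs exactly twice
      f <- sprintf("Filler%04d", seq_len(rest))
      nxt <- c(seq.int(2L, rest), 1L)
      fill <- lapply(seq_len(rest), function(j) c(f[j], f[nxt[j]]))
    } else {
      fill <- lapply(sprintf("Filler%04d", seq_len(rest)), identity)
    }
    txns <- c(txns, fill)
  }
  db <- transaction_db(txns)
  # constructive realizability check
  li <- match(lhs_label, db$labels); ri <- match(rhs_label, db$labels)
  has <- function(ids) sum(vapply(db$transactions,
                                  function(t) all(ids %in% t), logical(1)))
  stopifnot(db$n == n, has(li) == c_lhs, has(ri) == c_rhs,
            has(c(li, ri)) == c_joint)
  db
}
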