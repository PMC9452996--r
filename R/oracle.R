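# Reference miners used only for equivalence checking. Both are naive by
# design: the exhaustive enumerator checks every candidate subset against
# every transaction, and the classic level-wise miner counts with plain set
# membership — no Boolean matrix, no compression, no trie.

#' Exhaustive brute-force frequent-itemset miner
#'
#' Enumerates every non-empty subset of the vocabulary (guarded to m <= 20)
#' and counts containing transactions by direct set inclusion.
#'
#' @param db A [transaction_db()].
#' @param min_support Minimum support fraction in (0, 1].
#' @return An `itemset_index_table` identical in format to
#'   [mine_frequent()]'s.
#' @export
brute_force_frequent <- function(db, min_support) {
  stopifnot(inherits(db, "transaction_db"))
  if (db$m > 20L)
    stop("brute force refused: more than 20 items (2^m enumeration)",
         call. = FALSE)
  n <- db$n
  minc <- max(1L, min_count_for(min_support, n))
  # transactions as bitmasks so every subset check is still an explicit
  # containment test, just cheap
  tmask <- vapply(db$transactions, function(ids) sum(2^(ids - 1L)), 0)
  levels <- list()
  for (s in seq_len(2^db$m - 1)) {
    ids <- which(bitwAnd(s, 2^(seq_len(db$m) - 1L)) > 0)
    cnt <- sum(bitwAnd(tmask, s) == s)
    if (cnt >= minc) {
      k <- length(ids)
      if (length(levels) < k) levels[[k]] <- integer()
      levels[[k]][[itemset_key(ids)]] <- as.integer(cnt)
    }
  }
  # trim trailing empty levels and sort keys canonically
  while (length(levels) > 0L && length(levels[[length(levels)]]) == 0L)
    levels[[length(levels)]] <- NULL
  levels <- lapply(levels, function(lk) lk[order(names(lk), method = "radix")])
  if (length(levels) >= 1L)
    levels[[1L]] <- levels[[1L]][order(as.integer(names(levels[[1L]])))]
  new_index_table(levels, n, minc, db$labels)
}

#' Classic textbook Apriori
#'
#' Layer-by-layer candidate-generate-and-test with set-based counting (no
#' bit vectors, no compression, no Step-1 deletion) followed by rule
#' generation over all non-empty proper antecedents. Used as an independent
#' reference for the optimized pipeline; the optimization is meant to change
#' cost, never output.
#'
#' @param db A [transaction_db()].
#' @param params A [mining_params()]; `count_threshold` and `max_k` are
#'   ignored (the textbook algorithm has neither).
#' @return A list with `itemsets` (an `itemset_index_table`) and `rules`
#'   (a `herb_rules` data frame in the same format as [generate_rules()]).
#' @export
classic_apriori <- function(db, params = mining_params()) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  n <- db$n
  minc <- max(1L, min_count_for(params$min_support, n))
  txns <- db$transactions

  count_set <- function(ids)
    sum(vapply(txns, function(t) all(ids %in% t), logical(1)))

  levels <- list()
  l1 <- which(vapply(seq_len(db$m), function(i) count_set(i), 0L) >= minc)
  if (length(l1) > 0L) {
    levels[[1L]] <- stats::setNames(
      vapply(l1, count_set, 0L), as.character(l1))
    prev <- lapply(l1, function(i) i)
    k <- 2L
    repeat {
      cands <- list()
      for (a in seq_along(prev)) {
        for (b in seq_along(prev)) {
          if (a >= b) next
          u <- sort(union(prev[[a]], prev[[b]]))
          if (length(u) == k) cands[[itemset_key(u)]] <- u
        }
      }
      if (length(cands) == 0L) break
      cnt <- vapply(cands, count_set, 0L)
      keep <- cnt >= minc
      if (!any(keep)) break
      lk <- cnt[keep]
      levels[[k]] <- lk[order(names(lk), method = "radix")]
      prev <- cands[keep]
      k <- k + 1L
    }
  }
  table <- new_index_table(levels, n, minc, db$labels)

  # rule generation with direct recounts (independent of the trie path)
  lhs <- character(); rhs <- character()
  cj <- integer(); cl <- integer(); cr <- integer()
  for (k in seq_along(levels)) {
    if (k < 2L) next
    for (key in names(levels[[k]])) {
      z <- key_to_ids(key)
      cz <- levels[[k]][[key]]
      for (xsize in seq_len(k - 1L)) {
        for (pick in utils::combn(k, xsize, simplify = FALSE)) {
          x <- z[pick]; y <- z[-pick]
          cx <- count_set(x)
          if (cz / cx >= params$min_confidence) {
            lhs <- c(lhs, paste(db$labels[x], collapse = "+"))
            rhs <- c(rhs, paste(db$labels[y], collapse = "+"))
            cj <- c(cj, as.integer(cz)); cl <- c(cl, as.integer(cx))
            cr <- c(cr, as.integer(count_set(y)))
          }
        }
      }
    }
  }
  rules <- data.frame(lhs = lhs, rhs = rhs,
                      support = cj / n, confidence = cj / cl,
                      coverage = cl / n, lift = (cj / cl) / (cr / n),
                      count = cj, lhs_count = cl, rhs_count = cr,
                      stringsAsFactors = FALSE)
  rules <- rules[order(-rules$support, -rules$confidence, rules$lhs,
                       rules$rhs, method = "radix"), , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("herb_rules", "data.frame")
  attr(rules, "n_total") <- n
  list(itemsets = table, rules = rules)
}
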