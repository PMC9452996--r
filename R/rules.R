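# Trie over frequent itemsets and association-rule generation.
#
# The trie is keyed by canonical item order: a path from the root spells an
# ascending id sequence, and a node stores the support count when that path
# is a frequent itemset. Rule generation walks every frequent itemset of
# size >= 2, enumerates antecedents, and fetches subset counts from the
# trie instead of rescanning data.

#' Build a prefix tree over a frequent-itemset index table
#'
#' @param table An `itemset_index_table` from [mine_frequent()].
#' @return A `rule_trie`: nested environments with a `count` slot per
#'   frequent itemset.
#' @export
build_trie <- function(table) {
  stopifnot(inherits(table, "itemset_index_table"))
  root <- new.env(parent = emptyenv())
  for (k in seq_along(table$levels)) {
    lk <- table$levels[[k]]
    for (key in names(lk)) {
      node <- root
      for (id in key_to_ids(key)) {
        nm <- as.character(id)
        child <- node[[nm]]
        if (is.null(child)) {
          child <- new.env(parent = emptyenv())
          node[[nm]] <- child
        }
        node <- child
      }
      node$count <- lk[[key]]
    }
  }
  structure(list(root = root), class = "rule_trie")
}

#' Look up an itemset's support count in a trie
#'
#' @param trie A [build_trie()] result.
#' @param ids Integer item ids (any order).
#' @return The stored support count, or `NA_integer_` when the itemset is
#'   not frequent.
#' @export
trie_lookup <- function(trie, ids) {
  stopifnot(inherits(trie, "rule_trie"), length(ids) >= 1L)
  node <- trie$root
  for (id in sort(as.integer(ids))) {
    node <- node[[as.character(id)]]
    if (is.null(node)) return(NA_integer_)
  }
  if (is.null(node$count)) NA_integer_ else node$count
}

#' Association-rule metrics from contingency counts
#'
#' Given the joint count of X and Y, the marginal counts of X and Y, and the
#' transaction total n, returns the four standard metrics of the rule
#' X -> Y:
#' support = joint/n, confidence = joint/count(X), coverage = count(X)/n,
#' lift = confidence / (count(Y)/n).
#'
#' @param count_joint,count_lhs,count_rhs,n_total Non-negative integers with
#'   `0 < count_joint <= min(count_lhs, count_rhs) <= n_total`.
#' @return Named numeric vector `support, confidence, coverage, lift`.
#' @examples
#' rule_metrics(36, 49, 69, 238)  # support 0.1513, confidence 0.7347, ...
#' @export
rule_metrics <- function(count_joint, count_lhs, count_rhs, n_total) {
  if (!(count_joint > 0 && count_joint <= min(count_lhs, count_rhs) &&
        max(count_lhs, count_rhs) <= n_total))
    stop("invalid contingency counts: need 0 < joint <= min(lhs, rhs) <= n",
         call. = FALSE)
  c(support    = count_joint / n_total,
    confidence = count_joint / count_lhs,
    coverage   = count_lhs / n_total,
    lift       = (count_joint / count_lhs) / (count_rhs / n_total))
}

#' Generate strong association rules from a frequent-itemset table
#'
#' For every frequent itemset Z with at least two items and every non-empty
#' proper subset X of Z, the candidate rule X -> Z \ X is scored via trie
#' lookups (confidence = count(Z) / count(X)) and emitted when its
#' confidence reaches `min_confidence`. Antecedents of any size are allowed;
#' `max_rhs = 1` restricts to single-item consequents.
#'
#' @param table An `itemset_index_table`.
#' @param trie The matching [build_trie()] result (built on demand if
#'   `NULL`).
#' @param min_confidence Minimum confidence in (0, 1].
#' @param max_rhs Optional cap on consequent size.
#' @return A `herb_rules` data frame sorted by support then confidence
#'   (both descending), then canonical lhs/rhs: columns `lhs`, `rhs`
#'   (labels joined by `"+"`), `support`, `confidence`, `coverage`, `lift`,
#'   `count`, plus the integer marginals `lhs_count` and `rhs_count`.
#' @export
generate_rules <- function(table, trie = NULL, min_confidence = 0.60,
                           max_rhs = NULL) {
  stopifnot(inherits(table, "itemset_index_table"))
  if (is.null(trie)) trie <- build_trie(table)
  n <- table$n_total
  lhs <- character(); rhs <- character()
  cj <- integer(); cl <- integer(); cr <- integer()
  for (k in seq_along(table$levels)) {
    if (k < 2L) next
    lk <- table$levels[[k]]
    for (key in names(lk)) {
      z <- key_to_ids(key)
      cz <- lk[[key]]
      for (xsize in seq_len(k - 1L)) {
        if (!is.null(max_rhs) && k - xsize > max_rhs) next
        for (pick in utils::combn(k, xsize, simplify = FALSE)) {
          x <- z[pick]; y <- z[-pick]
          cx <- trie_lookup(trie, x)
          cy <- trie_lookup(trie, y)
          if (is.na(cx) || is.na(cy))
            stop("downward closure violated: subset of a frequent itemset ",
                 "missing from the trie", call. = FALSE)
          if (cz / cx >= min_confidence) {
            lhs <- c(lhs, paste(table$labels[x], collapse = "+"))
            rhs <- c(rhs, paste(table$labels[y], collapse = "+"))
            cj <- c(cj, cz); cl <- c(cl, cx); cr <- c(cr, cy)
          }
        }
      }
    }
  }
  out <- data.frame(lhs = lhs, rhs = rhs,
                    support = cj / n,
                    confidence = cj / cl,
                    coverage = cl / n,
                    lift = (cj / cl) / (cr / n),
                    count = cj, lhs_count = cl, rhs_count = cr,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, -out$confidence, out$lhs, out$rhs,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("herb_rules", "data.frame")
  attr(out, "n_total") <- n
  out
}

#' @export
print.herb_rules <- function(x, n = 10L, ...) {
  cat(sprintf("%d association rule(s) over %d transaction(s)\n",
              nrow(x), attr(x, "n_total")))
  if (nrow(x) > 0L) {
    show <- utils::head(as.data.frame(x)[
      c("lhs", "rhs", "support", "confidence", "coverage", "lift", "count")],
      n)
    num <- c("support", "confidence", "coverage", "lift")
    show[num] <- lapply(show[num], round, 8L)
    print(show)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}
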