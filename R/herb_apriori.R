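#' Mine herb association rules with the optimized Apriori pipeline
#'
#' The main entry point: runs the full optimized pipeline — rare-item
#' deletion, Boolean-matrix construction, level-wise bitwise mining with
#' row/column compression, trie-based rule generation — and returns one
#' object holding the frequent-itemset index table and the strong rules.
#'
#' Defaults reproduce the herbal prescription study settings: minimum
#' support 13% and minimum confidence 60%, with items occurring only once
#' deleted up front.
#'
#' @param db A [transaction_db()].
#' @param min_support Minimum support fraction in (0, 1].
#' @param min_confidence Minimum confidence fraction in (0, 1].
#' @param count_threshold Rare-item deletion threshold (Step 1); `0`
#'   disables it.
#' @param max_k Largest itemset size to mine.
#' @param max_rhs Optional cap on rule consequent size (`1` gives the
#'   single-consequent view of the published rule table).
#' @param use_row_compress,use_col_compress Compression toggles; outputs are
#'   identical either way.
#' @return An object of class `herb_apriori` with components `itemsets`
#'   (the index table), `rules` (a `herb_rules` data frame), `n_total`, `m`,
#'   `params` and `call`.
#' @examples
#' db <- transaction_db(list(c("A", "B"), c("A", "B"), "A", c("B", "C")))
#' fit <- herb_apriori(db, min_support = 0.5, min_confidence = 0.6,
#'                     count_threshold = 0)
#' fit$rules
#' @export
herb_apriori <- function(db, min_support = 0.13, min_confidence = 0.60,
                         count_threshold = 1L, max_k = Inf, max_rhs = NULL,
                         use_row_compress = TRUE, use_col_compress = TRUE) {
  params <- mining_params(min_support, min_confidence, count_threshold, max_k)
  table <- mine_frequent(db, params,
                         use_row_compress = use_row_compress,
                         use_col_compress = use_col_compress)
  rules <- generate_rules(table, min_confidence = min_confidence,
                          max_rhs = max_rhs)
  structure(
    list(itemsets = table, rules = rules, n_total = table$n_total,
         m = length(table$labels), params = params, call = match.call()),
    class = "herb_apriori"
  )
}

#' @export
print.herb_apriori <- function(x, ...) {
  cat("Optimized Apriori association-rule mining\n")
  cat(sprintf("  %d transactions, %d items after rare-item deletion\n",
              x$n_total, x$m))
  cat(sprintf("  min support %.4g (count >= %d), min confidence %.4g\n",
              x$params$min_support, x$itemsets$min_count,
              x$params$min_confidence))
  nsets <- sum(lengths(x$itemsets$levels))
  cat(sprintf("  %d frequent itemset(s) across %d level(s); %d rule(s)\n",
              nsets, length(x$itemsets$levels), nrow(x$rules)))
  invisible(x)
}

#' @export
summary.herb_apriori <- function(object, ...) {
  print(object)
  print(object$itemsets)
  print(object$rules, n = 20L)
  invisible(object)
}

#' @export
as.data.frame.herb_apriori <- function(x, ...) as.data.frame(x$rules)

#' Support/confidence scatter of mined rules
#'
#' Plots each rule at (support, confidence), point size scaled by lift —
#' the standard exploratory view of a rule set.
#'
#' @param x A [herb_apriori()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.herb_apriori <- function(x, ...) {
  r <- x$rules
  if (nrow(r) == 0L) stop("no rules to plot", call. = FALSE)
  graphics::plot(r$support, r$confidence,
                 cex = 0.5 + r$lift / max(r$lift),
                 xlab = "support", ylab = "confidence",
                 main = sprintf("%d association rules", nrow(r)), ...)
  invisible(x)
}
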