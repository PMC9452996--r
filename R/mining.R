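# Level-wise frequent-itemset mining over the bit-packed incidence matrix.
# Frequent itemsets live in a per-level "index table": level k maps each
# canonically ordered k-itemset to its support count.

itemset_key <- function(ids) paste(ids, collapse = " ")

key_to_ids <- function(key) as.integer(strsplit(key, " ", fixed = TRUE)[[1L]])

# absolute support-count threshold; the small fuzz guards against binary
# float artifacts (0.3 * 30 evaluating just above 9)
min_count_for <- function(min_support, n) {
  as.integer(ceiling(min_support * n - 1e-9))
}

new_index_table <- function(levels, n_total, min_count, labels) {
  structure(list(levels = levels, n_total = n_total,
                 min_count = min_count, labels = labels),
            class = "itemset_index_table")
}

#' Mining parameters
#'
#' Bundles the thresholds of the mining pipeline. Defaults are the ones used
#' for the herbal prescription study: minimum support 13%, minimum
#' confidence 60%.
#'
#' @param min_support Minimum support fraction in (0, 1].
#' @param min_confidence Minimum rule confidence in (0, 1].
#' @param count_threshold Rare-item deletion threshold for
#'   [prune_rare_items()]; `0` disables Step 1.
#' @param max_k Largest itemset size to mine; `Inf` for no cap.
#' @return A list of class `mining_params`.
#' @export
mining_params <- function(min_support = 0.13, min_confidence = 0.60,
                          count_threshold = 1L, max_k = Inf) {
  if (!(min_support > 0 && min_support <= 1))
    stop("min_support must be in (0, 1]", call. = FALSE)
  if (!(min_confidence > 0 && min_confidence <= 1))
    stop("min_confidence must be in (0, 1]", call. = FALSE)
  if (count_threshold < 0) stop("count_threshold must be >= 0", call. = FALSE)
  if (max_k < 1) stop("max_k must be >= 1", call. = FALSE)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 count_threshold = as.integer(count_threshold), max_k = max_k),
            class = "mining_params")
}

# join frequent (k-1)-itemsets sharing a (k-2)-prefix, then prune candidates
# with an infrequent (k-1)-subset (downward closure)
candidate_join <- function(prev_ids, prev_keys) {
  k1 <- length(prev_ids[[1L]])
  prefix <- vapply(prev_ids, function(x) itemset_key(x[-k1]), character(1))
  out <- list()
  for (grp in split(seq_along(prev_ids), prefix)) {
    if (length(grp) < 2L) next
    last <- sort(vapply(prev_ids[grp], function(x) x[k1], integer(1)))
    pre <- prev_ids[[grp[1L]]][-k1]
    for (a in seq_len(length(last) - 1L)) {
      for (b in seq.int(a + 1L, length(last))) {
        cand <- c(pre, last[a], last[b])
        ok <- TRUE
        for (drop in seq_len(k1 + 1L)) {
          if (!(itemset_key(cand[-drop]) %in% prev_keys)) { ok <- FALSE; break }
        }
        if (ok) out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Mine frequent itemsets with the optimized pipeline
#'
#' Runs rare-item deletion, builds the Boolean incidence matrix, and iterates
#' level-wise: candidates at level k come from joining frequent
#' (k-1)-itemsets on a shared (k-2)-prefix and pruning by downward closure;
#' supports are bitwise AND + popcount; row compression drops items absent
#' from every frequent (k-1)-itemset and column compression drops
#' transactions shorter than k before each level. Level-1 supports come
#' straight from the vocabulary occurrence counts (the first database scan);
#' the matrix build is the second and last scan.
#'
#' Supports are fractions of `n_total`, the transaction count entering the
#' matrix (after Step 1 dropped any emptied transactions). An itemset is
#' frequent iff its count is at least `ceiling(min_support * n_total)`.
#'
#' @param db A [transaction_db()].
#' @param params A [mining_params()] object (or individual thresholds via
#'   `...` arguments of [herb_apriori()]).
#' @param use_row_compress,use_col_compress Toggles for the two compressions;
#'   output is identical either way (they only change work done).
#' @return An `itemset_index_table`: `levels[[k]]` is a named integer vector
#'   of support counts keyed by space-separated item ids, plus `n_total`,
#'   `min_count` and the vocabulary `labels`.
#' @export
mine_frequent <- function(db, params = mining_params(),
                          use_row_compress = TRUE, use_col_compress = TRUE) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  if (params$count_threshold > 0L)
    db <- prune_rare_items(db, params$count_threshold)
  n <- db$n
  minc <- max(1L, min_count_for(params$min_support, n))

  levels <- list()
  freq1 <- which(db$counts >= minc)
  if (length(freq1) == 0L)
    return(new_index_table(list(), n, minc, db$labels))
  l1 <- stats::setNames(db$counts[freq1], as.character(freq1))
  levels[[1L]] <- l1[order(as.integer(names(l1)))]
  if (params$max_k <= 1)
    return(new_index_table(levels, n, minc, db$labels))

  mat <- build_matrix(db)
  k <- 2L
  prev_ids <- lapply(freq1, function(i) i)
  repeat {
    if (use_row_compress)
      mat <- row_compress(mat, unique(unlist(prev_ids, use.names = FALSE)))
    if (use_col_compress)
      mat <- col_compress(mat, k)
    prev_keys <- vapply(prev_ids, itemset_key, character(1))
    cands <- candidate_join(prev_ids, prev_keys)
    if (length(cands) == 0L) break
    counts <- vapply(cands, function(s) support_count(mat, s), integer(1))
    keep <- counts >= minc
    if (!any(keep)) break
    lk <- stats::setNames(counts[keep],
                          vapply(cands[keep], itemset_key, character(1)))
    levels[[k]] <- lk[order(names(lk), method = "radix")]
    prev_ids <- cands[keep]
    k <- k + 1L
    if (k > params$max_k) break
  }
  new_index_table(levels, n, minc, db$labels)
}

#' @export
print.itemset_index_table <- function(x, ...) {
  cat(sprintf("Frequent-itemset index table (n = %d, min count = %d)\n",
              x$n_total, x$min_count))
  if (length(x$levels) == 0L) {
    cat("  <empty>\n")
  } else {
    for (k in seq_along(x$levels))
      cat(sprintf("  k = %d: %d itemset(s)\n", k, length(x$levels[[k]])))
  }
  invisible(x)
}

#' @export
as.data.frame.itemset_index_table <- function(x, ...) {
  rows <- list()
  for (k in seq_along(x$levels)) {
    lk <- x$levels[[k]]
    if (length(lk) == 0L) next
    sets <- vapply(names(lk), function(key)
      paste(x$labels[key_to_ids(key)], collapse = "+"), character(1))
    rows[[k]] <- data.frame(k = k, itemset = unname(sets),
                            count = unname(lk),
                            support = unname(lk) / x$n_total,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(k = integer(), itemset = character(),
                      count = integer(), support = numeric()))
  do.call(rbind, rows)
}

#' Write an index table to CSV
#'
#' Columns `k, itemset, count, support`; items within a set joined by `"+"`.
#'
#' @param table An `itemset_index_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itemsets_csv <- function(table, path) {
  stopifnot(inherits(table, "itemset_index_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# flat named count lookup across levels, used by oracles and tests
table_lookup <- function(table, ids) {
  k <- length(ids)
  if (k > length(table$levels)) return(NA_integer_)
  v <- unname(table$levels[[k]][itemset_key(sort(ids))])
  if (length(v) == 0L) NA_integer_ else as.integer(v)
}
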