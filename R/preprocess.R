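# Bit-packed Boolean incidence matrix and the two Apriori preprocessing
# steps: rare-item deletion (Step 1) and row/column compression (Step 2).
# One raw (byte) vector per item row; transaction j maps to bit j. Only AND
# and popcount over live columns are part of the contract; byte layout is
# internal.

# byte popcount lookup, built once at load
POPCOUNT_BYTE <- vapply(0:255, function(b) sum(bitwAnd(b, 2L^(0:7)) > 0L), 0L)

pack_bits <- function(bits) {
  # logical vector -> raw vector, bit j of the stream = bits[j]
  pad <- (-length(bits)) %% 8L
  packBits(c(bits, rep(FALSE, pad)), type = "raw")
}

unpack_bits <- function(r, n) {
  as.integer(rawToBits(r))[seq_len(n)]
}

popcount_raw <- function(r) {
  sum(POPCOUNT_BYTE[as.integer(r) + 1L])
}

#' Delete rare items from a transaction database
#'
#' Apriori preprocessing Step 1: every item whose total occurrence count is
#' at most `count_threshold` is removed from all transactions, transactions
#' emptied by the removal are dropped, and the pass repeats until a fixed
#' point (dropping a transaction can push further items under the
#' threshold). An item below absolute minimum support can never join a
#' frequent itemset, so with `count_threshold` below the support count
#' threshold the frequent itemsets are unchanged; dropped transactions do,
#' however, shrink the denominator used for support fractions downstream.
#'
#' @param db A [transaction_db()].
#' @param count_threshold Remove items occurring in `<= count_threshold`
#'   transactions. `0` is the identity. Default `1` (items seen once).
#' @return A pruned [transaction_db()].
#' @export
prune_rare_items <- function(db, count_threshold = 1L) {
  stopifnot(inherits(db, "transaction_db"))
  count_threshold <- as.integer(count_threshold)
  if (count_threshold < 0L) stop("count_threshold must be >= 0", call. = FALSE)
  if (count_threshold == 0L) return(db)
  labels <- db$labels
  txns <- lapply(db$transactions, function(ids) labels[ids])
  repeat {
    cnt <- table(unlist(txns, use.names = FALSE))
    drop <- names(cnt)[cnt <= count_threshold]
    if (length(drop) == 0L) break
    txns <- lapply(txns, function(x) x[!(x %in% drop)])
    txns <- txns[lengths(txns) > 0L]
    if (length(txns) == 0L)
      stop("empty database after pruning", call. = FALSE)
  }
  transaction_db(txns)
}

#' Build the Boolean incidence matrix of a transaction database
#'
#' One bit row per vocabulary item, one bit column per transaction: bit
#' `(i, j)` is 1 iff item `i` belongs to transaction `j`. Rows are raw
#' vectors so that joint supports come from byte-wise AND plus popcount.
#' The matrix carries live-row and live-column masks for compression.
#'
#' @param db A non-empty [transaction_db()].
#' @return An object of class `bool_matrix`.
#' @export
build_matrix <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  if (db$n == 0L) stop("empty database", call. = FALSE)
  n <- db$n
  inc <- matrix(FALSE, nrow = n, ncol = db$m)
  for (j in seq_len(n)) inc[j, db$transactions[[j]]] <- TRUE
  rows <- lapply(seq_len(db$m), function(i) pack_bits(inc[, i]))
  structure(
    list(rows = rows, labels = db$labels, n_total = n,
         live_items = rep(TRUE, db$m), col_mask = pack_bits(rep(TRUE, n))),
    class = "bool_matrix"
  )
}

#' @export
print.bool_matrix <- function(x, ...) {
  cat(sprintf("Boolean matrix: %d item rows (%d live), %d columns (%d live)\n",
              length(x$rows), sum(x$live_items), x$n_total,
              popcount_raw(x$col_mask)))
  invisible(x)
}

#' Bitwise support count of an itemset
#'
#' ANDs the itemset's bit rows and the live-column mask and popcounts the
#' result: the number of live transactions containing every item of the set.
#'
#' @param mat A [build_matrix()] result.
#' @param itemset Integer item ids (vocabulary indices), non-empty, all live.
#' @return Integer support count.
#' @export
support_count <- function(mat, itemset) {
  stopifnot(inherits(mat, "bool_matrix"), length(itemset) >= 1L)
  if (any(itemset < 1L | itemset > length(mat$rows)) ||
      !all(mat$live_items[itemset]))
    stop("itemset refers to an item not live in the matrix", call. = FALSE)
  acc <- mat$rows[[itemset[1L]]]
  for (i in itemset[-1L]) acc <- acc & mat$rows[[i]]
  popcount_raw(acc & mat$col_mask)
}

#' Row compression
#'
#' Removes from the live-row mask every item that appears in no frequent
#' itemset at the current level: supersets of infrequent itemsets are
#' infrequent, so those rows can never contribute again.
#'
#' @param mat A [build_matrix()] result.
#' @param frequent_items Integer ids of items occurring in at least one
#'   frequent itemset at the current level.
#' @return The matrix with its row mask narrowed.
#' @export
row_compress <- function(mat, frequent_items) {
  stopifnot(inherits(mat, "bool_matrix"))
  keep <- logical(length(mat$rows))
  keep[frequent_items] <- TRUE
  mat$live_items <- mat$live_items & keep
  mat
}

#' Column compression
#'
#' Removes from the live-column mask every transaction with fewer than `k`
#' live items: such a transaction cannot contain any k-itemset, so dropping
#' it leaves all supports of itemsets of size >= k unchanged.
#'
#' @param mat A [build_matrix()] result.
#' @param k Current itemset size, `>= 1`.
#' @return The matrix with its column mask narrowed.
#' @export
col_compress <- function(mat, k) {
  stopifnot(inherits(mat, "bool_matrix"), k >= 1L)
  n <- mat$n_total
  len <- integer(n)
  for (i in which(mat$live_items))
    len <- len + unpack_bits(mat$rows[[i]], n)
  live_cols <- unpack_bits(mat$col_mask, n) == 1L
  mat$col_mask <- pack_bits(live_cols & (len >= k))
  mat
}
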