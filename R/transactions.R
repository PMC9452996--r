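#' Transaction databases of herbal prescriptions
#'
#' A `transaction_db` holds an ordered collection of transactions (each a
#' duplicate-free set of items, e.g. the herbs of one prescription) together
#' with an item vocabulary. Items are stored as integer ids into the
#' vocabulary; the vocabulary is kept in canonical (byte-lexicographic) label
#' order so that every itemset, report and rule prints deterministically.
#'
#' @param items A list of character vectors, one per transaction; each vector
#'   names the items of that transaction. Duplicates within a transaction are
#'   collapsed (set semantics); empty transactions are not allowed.
#'
#' @return An object of class `transaction_db` with components:
#'   \describe{
#'     \item{labels}{character vector of item labels, canonical order}
#'     \item{transactions}{list of sorted integer id vectors}
#'     \item{counts}{integer occurrence count per vocabulary item}
#'     \item{n}{number of transactions}
#'     \item{m}{number of vocabulary items}
#'   }
#' @examples
#' db <- transaction_db(list(c("Gancao", "Xingren"), "Gancao"))
#' db$n
#' item_counts(db)
#' @export
transaction_db <- function(items) {
  if (!is.list(items) || length(items) == 0L)
    stop("empty database: need at least one transaction", call. = FALSE)
  items <- lapply(items, function(x) unique(trimws(as.character(x))))
  items <- lapply(items, function(x) x[nzchar(x)])
  if (any(lengths(items) == 0L))
    stop("transactions must be non-empty", call. = FALSE)
  labels <- sort(unique(unlist(items, use.names = FALSE)), method = "radix")
  txns <- lapply(items, function(x) sort(match(x, labels)))
  new_transaction_db(labels, txns)
}

# low-level constructor: labels already canonical, txns sorted id vectors
new_transaction_db <- function(labels, txns) {
  counts <- tabulate(unlist(txns, use.names = FALSE), nbins = length(labels))
  structure(
    list(labels = labels, transactions = txns, counts = as.integer(counts),
         n = length(txns), m = length(labels)),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("Transaction database: %d transactions, %d items\n", x$n, x$m))
  sizes <- lengths(x$transactions)
  cat(sprintf("  transaction sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  top <- utils::head(order(-x$counts, x$labels, method = "radix"), 5L)
  cat("  most frequent items:",
      paste0(x$labels[top], " (", x$counts[top], ")", collapse = ", "), "\n")
  invisible(x)
}

#' Item occurrence counts
#'
#' @param db A [transaction_db()].
#' @return Named integer vector: per-item number of transactions containing
#'   the item, in canonical vocabulary order.
#' @export
item_counts <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  stats::setNames(db$counts, db$labels)
}

#' Read a transaction database from a basket file
#'
#' One transaction per non-blank line; items separated by `delimiter` and
#' whitespace-trimmed. Duplicate items within a line collapse to a set; blank
#' lines are skipped with a warning.
#'
#' @param path Path to a basket-format text file (UTF-8).
#' @param delimiter Item separator, default `","`.
#' @return A [transaction_db()].
#' @export
load_basket <- function(path, delimiter = ",") {
  if (!nzchar(delimiter)) stop("delimiter must be non-empty", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank))
    warning(sum(blank), " blank line(s) skipped in ", path, call. = FALSE)
  lines <- lines[!blank]
  if (length(lines) == 0L)
    stop("empty database: no non-blank lines in ", path, call. = FALSE)
  transaction_db(strsplit(lines, delimiter, fixed = TRUE))
}

#' Write a transaction database to a basket file
#'
#' @inheritParams load_basket
#' @param db A [transaction_db()].
#' @return `path`, invisibly.
#' @export
write_basket <- function(db, path, delimiter = ",") {
  stopifnot(inherits(db, "transaction_db"))
  lines <- vapply(db$transactions,
                  function(ids) paste(db$labels[ids], collapse = delimiter),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a transaction database from a binary incidence-matrix CSV
#'
#' Header row gives the item labels; body cells are 0/1, one transaction per
#' row (1 = item present). All-zero rows are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @return A [transaction_db()].
#' @export
load_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  labels <- trimws(names(df))
  if (anyDuplicated(labels))
    stop("duplicate item label in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty database: no data rows", call. = FALSE)
  mat <- matrix(trimws(as.matrix(df)), nrow = nrow(df))
  bad <- !(mat %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    r <- (idx - 1L) %% nrow(mat) + 1L
    c_ <- (idx - 1L) %/% nrow(mat) + 1L
    stop(sprintf("non-binary cell '%s' at row %d, column '%s'",
                 mat[r, c_], r, labels[c_]), call. = FALSE)
  }
  inc <- mat == "1"
  empty <- rowSums(inc) == 0L
  if (any(empty))
    warning(sum(empty), " all-zero row(s) dropped", call. = FALSE)
  inc <- inc[!empty, , drop = FALSE]
  if (nrow(inc) == 0L)
    stop("empty database: all rows are zero", call. = FALSE)
  transaction_db(apply(inc, 1L, function(r) labels[r], simplify = FALSE))
}

#' Write a transaction database as a binary incidence-matrix CSV
#'
#' Columns are the vocabulary in canonical order; row `r` has 1 in the
#' columns of transaction `r`'s items. `load_matrix_csv()` round-trips the
#' result exactly.
#'
#' @param db A [transaction_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  if (db$n == 0L) stop("empty database", call. = FALSE)
  inc <- matrix(0L, nrow = db$n, ncol = db$m)
  for (r in seq_len(db$n)) inc[r, db$transactions[[r]]] <- 1L
  colnames(inc) <- db$labels
  utils::write.csv(inc, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
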