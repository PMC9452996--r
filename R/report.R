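#' Item frequency report
#'
#' Ranks items by the number of transactions containing them — the
#' frequency analysis used to surface high-frequency core herbs.
#'
#' @param db A [transaction_db()].
#' @param top_k Number of items to report (capped at the vocabulary size).
#' @return A data frame with columns `item`, `count`, `fraction`
#'   (`count / n`), sorted by count descending, ties broken by canonical
#'   label order.
#' @export
frequency_report <- function(db, top_k = 20L) {
  stopifnot(inherits(db, "transaction_db"), top_k >= 1L)
  ord <- order(-db$counts, db$labels, method = "radix")
  ord <- utils::head(ord, top_k)
  data.frame(item = db$labels[ord], count = db$counts[ord],
             fraction = db$counts[ord] / db$n, stringsAsFactors = FALSE)
}

#' Export association rules to CSV
#'
#' Writes the seven standard columns
#' `lhs,rhs,support,confidence,coverage,lift,count` (itemsets joined by
#' `"+"`, metrics to 8 decimals), mirroring the published rule-table
#' layout.
#'
#' @param rules A `herb_rules` data frame from [generate_rules()] or a
#'   [herb_apriori()] fit's `$rules`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_rules_csv <- function(rules, path) {
  stopifnot(inherits(rules, "data.frame"))
  if (nrow(rules) == 0L)
    warning("no rules to export; writing header only", call. = FALSE)
  out <- as.data.frame(rules)[
    , c("lhs", "rhs", "support", "confidence", "coverage", "lift", "count"),
    drop = FALSE]
  for (col in c("support", "confidence", "coverage", "lift"))
    out[[col]] <- sprintf("%.8f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a rule CSV written by [export_rules_csv()]
#'
#' @param path Path to the CSV.
#' @return A data frame with the seven standard columns, metrics numeric.
#' @export
read_rules_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lhs", "rhs", "support", "confidence", "coverage", "lift", "count")
  if (!all(need %in% names(df)))
    stop("not a rule table: missing columns", call. = FALSE)
  for (col in c("support", "confidence", "coverage", "lift"))
    df[[col]] <- as.numeric(df[[col]])
  df$count <- as.integer(df$count)
  df[need]
}
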