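## Two-library comparison of annotation term counts: Fisher's exact test
## per term with Benjamini-Hochberg false discovery rate control.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value for the 2x2 contingency table
#' `rbind(c(a, b), c(c, d))` under fixed margins, using the "probability at
#' most that of the observed table" convention: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param a,b,c,d non-negative cell counts (term/not-term x library A/B).
#' @return The two-sided p-value, in (0, 1].
#' @examples
#' fisherExactTwoSided(5, 5, 5, 5)   # 1
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (sum(counts) == 0)
        stop("all-zero table: no data to test")
    stats::fisher.test(matrix(as.integer(counts), nrow = 2,
                              byrow = TRUE))$p.value
}

#' Compare annotation-term counts between two libraries
#'
#' For each term, tests the 2x2 table (term / not-term x library A / B)
#' with [fisherExactTwoSided()] and adjusts across all terms by
#' Benjamini-Hochberg; rows with adjusted p at most `fdrLevel` are flagged.
#' Direction is `over` when the term's frequency in library A exceeds that
#' in B, `under` when lower, `equal` otherwise.
#'
#' @param table a data.frame with columns `term_id`, optionally `label`,
#'   `count_a`, `count_b` (term occurrences per library).
#' @param totalA,totalB total annotated contigs per library.
#' @param fdrLevel false discovery rate threshold (default 0.01).
#' @return A data.frame with one row per term: term_id, label, a, b, c, d,
#'   p, q, direction, flagged; ordered as the input.
#' @export
compareTermLibraries <- function(table, totalA, totalB, fdrLevel = 0.01) {
    req <- c("term_id", "count_a", "count_b")
    if (!all(req %in% names(table)))
        stop("table needs columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(table$term_id))
        stop("duplicate term ids: ",
             paste(unique(table$term_id[duplicated(table$term_id)]),
                   collapse = ", "))
    if (totalA <= 0 || totalB <= 0) stop("library totals must be positive")
    if (any(table$count_a > totalA) || any(table$count_b > totalB))
        stop("term counts cannot exceed library totals")
    n <- nrow(table)
    a <- as.integer(table$count_a)
    c_ <- as.integer(table$count_b)
    b <- as.integer(totalA) - a
    d <- as.integer(totalB) - c_
    p <- vapply(seq_len(n),
                function(i) fisherExactTwoSided(a[i], b[i], c_[i], d[i]),
                numeric(1))
    q <- p.adjust(p, method = "BH")
    fA <- a / totalA
    fB <- c_ / totalB
    data.frame(term_id = table$term_id,
               label = if ("label" %in% names(table)) table$label
                   else NA_character_,
               a = a, b = b, c = c_, d = d, p = p, q = q,
               direction = ifelse(fA > fB, "over",
                                  ifelse(fA < fB, "under", "equal")),
               flagged = q <= fdrLevel)
}

#' Read / write term-count tables as TSV
#'
#' The on-disk layout is tab-separated with a header:
#' `term_id  label  count_a  count_b`. Term ids in `GO:NNNNNNN` form are
#' validated syntactically (not resolved against an ontology).
#'
#' @param path file path.
#' @return `readTermTable` returns the data.frame.
#' @export
readTermTable <- function(path) {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "")
    goLike <- grepl("^GO:", tab$term_id)
    bad <- goLike & !grepl("^GO:[0-9]{7}$", tab$term_id)
    if (any(bad))
        stop("malformed GO term id(s): ",
             paste(head(tab$term_id[bad], 3), collapse = ", "))
    tab
}

#' @param table a term-count (or result) data.frame.
#' @rdname readTermTable
#' @return `writeTermTable` returns `path` invisibly.
#' @export
writeTermTable <- function(table, path) {
    tab <- table
    for (cl in names(tab)) if (is.list(tab[[cl]])) tab[[cl]] <- NULL
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
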