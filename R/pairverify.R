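## Verification stage: full-contig overlap alignment of each candidate
## pair, requiring zero mismatches and zero internal gaps across the whole
## mutual overlap with flush (end-to-end) extension.

.overlapScores <- local({
    mat <- NULL
    function() {
        if (is.null(mat)) {
            letters5 <- c("A", "C", "G", "T", "N")
            m <- matrix(-2, 5, 5, dimnames = list(letters5, letters5))
            diag(m) <- 1
            # N never matches anything, including N
            m["N", "N"] <- -2
            mat <<- m
        }
        mat
    }
})

#' Overlap-align two contigs and judge the pair
#'
#' Optimal end-gap-free (overlap) global alignment under match +1,
#' mismatch -2, gap -4 per gapped base. The verdict is `accepted` only when
#' the aligned mutual overlap contains no mismatches (N counts as a
#' mismatch, even against N) and no internal gaps and the alignment is
#' flush, i.e. reaches a contig end on both sides so that terminal
#' unaligned sequence occurs only as dangling overhangs. Pairs whose
#' optimal alignment stops short of the contig ends (the exact core does
#' not extend) are `rejected_nonextension`.
#'
#' @param a,b contig sequences (character or `DNAString`); `b` is
#'   reverse-complemented first when `strand` is `"-"`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row data.frame: strand, overlap_len, n_mismatch,
#'   n_internal_gap, flush_left, flush_right, score, verdict.
#' @examples
#' overlapAlign("ACGTACGTAA", "ACGTACGTAA")$verdict
#' @export
overlapAlign <- function(a, b, strand = "+") {
    a <- toupper(as.character(a))
    b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
    bb <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    else b
    al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(bb),
        type = "overlap", substitutionMatrix = .overlapScores(),
        gapOpening = 0, gapExtension = 4)
    pat <- as.character(Biostrings::pattern(al))
    sub <- as.character(Biostrings::subject(al))
    if (!nzchar(pat)) {
        return(data.frame(strand = strand, overlap_len = 0L,
                          n_mismatch = 0L, n_internal_gap = 0L,
                          flush_left = FALSE, flush_right = FALSE,
                          score = Biostrings::score(al),
                          verdict = "rejected_nonextension"))
    }
    pc <- strsplit(pat, "")[[1]]
    sc <- strsplit(sub, "")[[1]]
    gap <- pc == "-" | sc == "-"
    nMis <- sum(!gap & (pc != sc | pc == "N" | sc == "N"))
    nGap <- sum(gap)
    qs <- IRanges::start(Biostrings::pattern(al))
    qe <- IRanges::end(Biostrings::pattern(al))
    ss <- IRanges::start(Biostrings::subject(al))
    se <- IRanges::end(Biostrings::subject(al))
    flushL <- qs == 1L || ss == 1L
    flushR <- qe == nchar(a) || se == nchar(bb)
    verdict <- if (nMis > 0) "rejected_mismatch"
        else if (nGap > 0) "rejected_gap"
        else if (!flushL || !flushR) "rejected_nonextension"
        else "accepted"
    data.frame(strand = strand,
               overlap_len = min(qe - qs + 1L, se - ss + 1L),
               n_mismatch = as.integer(nMis),
               n_internal_gap = as.integer(nGap),
               flush_left = flushL, flush_right = flushR,
               score = Biostrings::score(al), verdict = verdict)
}

#' Verify candidate comparisons by full-contig overlap alignment
#'
#' Each query-subject pair from the candidate comparisons is aligned once
#' (multiple matches between the same pair are deduplicated; when matches
#' were found on both strands the better-scoring strand is kept, ties going
#' to plus). Pairs failing the zero-mismatch / zero-gap / flush criteria are
#' retained with their rejection reason. Rows are ordered by (query id,
#' subject id).
#'
#' @param comparisons the list returned by [filterCandidatePairs()], or its
#'   `comparisons` data.frame.
#' @param libraryA,libraryB the query and subject [ContigLibrary-class]
#'   objects.
#' @return A data.frame of pair alignments with a `verdict` column;
#'   accepted pairs are `verdict == "accepted"`.
#' @export
verifyComparisons <- function(comparisons, libraryA, libraryB) {
    comp <- if (is.data.frame(comparisons)) comparisons
        else comparisons$comparisons
    empty <- data.frame(query_id = character(), subject_id = character(),
                        strand = character(), overlap_len = integer(),
                        n_mismatch = integer(), n_internal_gap = integer(),
                        flush_left = logical(), flush_right = logical(),
                        score = numeric(), verdict = character())
    if (is.null(comp) || !nrow(comp)) return(empty)
    aSeq <- as.character(contigs(libraryA))
    bSeq <- as.character(contigs(libraryB))
    missing <- setdiff(comp$query_id, names(aSeq))
    if (length(missing))
        stop("comparison references unknown query contig(s): ",
             paste(head(missing, 3), collapse = ", "))
    missing <- setdiff(comp$subject_id, names(bSeq))
    if (length(missing))
        stop("comparison references unknown subject contig(s): ",
             paste(head(missing, 3), collapse = ", "))
    key <- paste(comp$query_id, comp$subject_id, sep = "\r")
    rows <- lapply(split(seq_len(nrow(comp)), key), function(idx) {
        qid <- comp$query_id[idx[1]]
        sid <- comp$subject_id[idx[1]]
        best <- NULL
        for (st in sort(unique(comp$strand[idx]))) {  # "+" before "-"
            r <- overlapAlign(aSeq[[qid]], bSeq[[sid]], st)
            if (is.null(best) || r$score > best$score) best <- r
        }
        cbind(data.frame(query_id = qid, subject_id = sid), best)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize the accepted inter-genotype contig pairs
#'
#' Reports the counts and overlap statistics the protocol tracks for its
#' verified candidates: number of accepted pairs, distinct query/subject
#' contigs, mean/min/max overlap length (mean both exact and rounded to the
#' nearest bp), and, when read counts are available, the mean read count of
#' the contigs involved.
#'
#' @param aligned a pair-alignment data.frame from [verifyComparisons()]
#'   (any non-accepted rows are ignored).
#' @param libraryA,libraryB optional [ContigLibrary-class] objects used for
#'   the read-count average.
#' @return A list with n_accepted_pairs, n_unique_query, n_unique_subject,
#'   mean_overlap, mean_overlap_bp (rounded), min_overlap, max_overlap,
#'   mean_read_count and the flag means_defined.
#' @export
summarizeCandidates <- function(aligned, libraryA = NULL, libraryB = NULL) {
    acc <- if (!is.null(aligned$verdict))
        aligned[aligned$verdict == "accepted", , drop = FALSE]
    else aligned
    n <- nrow(acc)
    if (!n) {
        return(list(n_accepted_pairs = 0L, n_unique_query = 0L,
                    n_unique_subject = 0L, mean_overlap = NA_real_,
                    mean_overlap_bp = NA_integer_, min_overlap = NA_integer_,
                    max_overlap = NA_integer_, mean_read_count = NA_real_,
                    means_defined = FALSE))
    }
    rc <- NA_real_
    if (!is.null(libraryA) && !is.null(libraryB)) {
        counts <- c(readCounts(libraryA)[unique(acc$query_id)],
                    readCounts(libraryB)[unique(acc$subject_id)])
        if (any(!is.na(counts))) rc <- mean(counts, na.rm = TRUE)
    }
    list(n_accepted_pairs = n,
         n_unique_query = length(unique(acc$query_id)),
         n_unique_subject = length(unique(acc$subject_id)),
         mean_overlap = mean(acc$overlap_len),
         mean_overlap_bp = as.integer(round(mean(acc$overlap_len))),
         min_overlap = min(acc$overlap_len),
         max_overlap = max(acc$overlap_len),
         mean_read_count = rc, means_defined = TRUE)
}
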