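## Candidate identification: maximal exact matches between two contig
## libraries, Karlin-Altschul scoring, and the length/identity/E-value
## filter that defines the candidate comparisons.

.asStringSet <- function(x) {
    if (methods::is(x, "ContigLibrary")) return(contigs(x))
    if (methods::is(x, "DNAStringSet")) return(x)
    Biostrings::DNAStringSet(toupper(x))
}

#' Find all maximal exact matches between two libraries
#'
#' Returns every maximal exact common substring of length at least `minLen`
#' between any query and any subject contig, on both strands. A match is
#' maximal when it cannot be extended by one base on either side without a
#' mismatch (N mismatches everything, including N) or running off a contig
#' end. Matching is seeded with `minLen`-mers, so each maximal match is
#' found exactly once from its leftmost seed. Hits carry an ungapped score
#' (`reward * length`), a Karlin-Altschul E-value with m = query length and
#' n = total subject-library length, and identity 1. Rows are ordered by
#' (query id, subject id, qstart).
#'
#' Subject coordinates are always reported on the forward strand
#' (`sstart <= send`); minus-strand hits are flagged in `strand` and
#' rendered with `sstart > send` only by [writeHitsTabular()].
#'
#' @param queries,subjects [ContigLibrary-class] objects (or named
#'   `DNAStringSet`/character vectors).
#' @param minLen minimum match length in bp (>= 1).
#' @param scoring a [ScoringParams-class] used for scores and E-values.
#' @return A data.frame with columns query_id, subject_id, strand, qstart,
#'   qend, sstart, send, length, identity, mismatches, gapopens, score,
#'   bitscore, evalue. Coordinates are 1-based inclusive.
#' @examples
#' q <- contigLibrary("A", c(q1 = "ACGTACGTACGTACGTACGT"))
#' s <- contigLibrary("B", c(s1 = "TTACGTACGTACGTACGTACGTTT"))
#' findExactMatches(q, s, minLen = 12)
#' @export
findExactMatches <- function(queries, subjects, minLen,
                             scoring = scoringParams()) {
    if (minLen < 1) stop("minLen must be >= 1")
    q <- .asStringSet(queries)
    s <- .asStringSet(subjects)
    if (!length(q) || !length(s)) return(.emptyHits())
    qc <- as.character(q)
    sc <- as.character(s)
    slen <- nchar(sc)
    nTotal <- sum(as.numeric(slen))

    plus <- mem_scan_cpp(qc, sc, as.integer(minLen))
    rcsc <- as.character(Biostrings::reverseComplement(s))
    minus <- mem_scan_cpp(qc, rcsc, as.integer(minLen))

    build <- function(raw, strand) {
        if (!nrow(raw)) return(NULL)
        L <- raw$length
        if (strand == "+") {
            sstart <- raw$sstart
            send <- raw$sstart + L - 1L
        } else {
            # coordinates on the reverse complement -> forward strand
            sl <- slen[raw$sidx]
            sstart <- sl - (raw$sstart + L - 1L) + 1L
            send <- sl - raw$sstart + 1L
        }
        data.frame(query_id = names(q)[raw$qidx],
                   subject_id = names(s)[raw$sidx], strand = strand,
                   qstart = raw$qstart, qend = raw$qstart + L - 1L,
                   sstart = sstart, send = send, length = L,
                   identity = 1, mismatches = 0L, gapopens = 0L,
                   qlen = nchar(qc)[raw$qidx])
    }
    hits <- rbind(build(plus, "+"), build(minus, "-"))
    if (is.null(hits) || !nrow(hits)) return(.emptyHits())
    sc0 <- scoring@reward * hits$length
    ka <- karlinAltschulEvalue(sc0, scoring, m = hits$qlen, n = nTotal)
    hits$score <- sc0
    hits$bitscore <- ka$bitscore
    hits$evalue <- ka$evalue
    hits$qlen <- NULL
    hits <- hits[order(hits$query_id, hits$subject_id, hits$qstart,
                       hits$strand, hits$sstart), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

.emptyHits <- function() {
    data.frame(query_id = character(), subject_id = character(),
               strand = character(), qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(), length = integer(),
               identity = numeric(), mismatches = integer(),
               gapopens = integer(), score = numeric(), bitscore = numeric(),
               evalue = numeric())
}

#' Karlin-Altschul E-value and bit score for an ungapped score
#'
#' \eqn{E = K m n e^{-\lambda S}} with the bit score
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}. E is strictly decreasing in S and
#' linear in both effective lengths.
#'
#' @param score ungapped alignment score(s), in score units.
#' @param scoring a [ScoringParams-class] supplying lambda and K.
#' @param m effective query length, bp.
#' @param n effective database (subject-library) length, bp.
#' @return A list with numeric vectors `evalue` and `bitscore`.
#' @examples
#' karlinAltschulEvalue(100, scoringParams(), m = 250, n = 6.6e6)
#' @export
karlinAltschulEvalue <- function(score, scoring = scoringParams(), m, n) {
    if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
    lam <- scoring@lambda
    K <- scoring@K
    list(evalue = K * m * n * exp(-lam * score),
         bitscore = (lam * score - log(K)) / log(2))
}

#' Filter exact-match hits into candidate comparisons
#'
#' Applies the funnel's primary filter: identity at least `minIdentity`,
#' match length at least `minExactLen`, and E-value at most
#' `eThresholdPrimary`. Each retained hit is one candidate comparison (a
#' query-subject pair can contribute several comparisons through distinct
#' matches). Also reports the distinct query and subject contig counts, the
#' quantities the experimental protocol tracks alongside the comparison
#' count.
#'
#' @param hits a hit data.frame from [findExactMatches()].
#' @param config a [PipelineConfig-class].
#' @return A list with elements `comparisons` (the retained hit rows),
#'   `nComparisons`, `nUniqueQuery`, `nUniqueSubject`.
#' @export
filterCandidatePairs <- function(hits, config = pipelineConfig()) {
    if (is.null(hits) || !nrow(hits)) {
        return(list(comparisons = .emptyHits(), nComparisons = 0L,
                    nUniqueQuery = 0L, nUniqueSubject = 0L))
    }
    keep <- hits$identity >= config@minIdentity &
        hits$length >= config@minExactLen &
        hits$evalue <= config@eThresholdPrimary
    comp <- hits[keep, , drop = FALSE]
    rownames(comp) <- NULL
    list(comparisons = comp, nComparisons = nrow(comp),
         nUniqueQuery = length(unique(comp$query_id)),
         nUniqueSubject = length(unique(comp$subject_id)))
}
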