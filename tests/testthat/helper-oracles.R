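# Independent oracles used to validate the implementation: a quadratic
# all-common-substrings enumerator, a full dynamic-programming overlap
# aligner with traceback, and an exhaustive hypergeometric enumeration for
# Fisher's test. All are deliberately written without reference to the
# package internals.

rseq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]),
                                   collapse = ""))
}

# all maximal exact common substrings >= minLen between one query and one
# subject (plus strand), via the classic run-length diagonal DP
.oracleMemsOne <- function(q, s, minLen) {
    qa <- strsplit(q, "")[[1]]
    sa <- strsplit(s, "")[[1]]
    m <- length(qa); n <- length(sa)
    ok_q <- qa %in% c("A", "C", "G", "T")
    L <- matrix(0L, m + 1L, n + 1L)
    for (i in seq_len(m)) {
        hit <- ok_q[i] & (sa == qa[i])
        L[i + 1L, 2:(n + 1L)] <- ifelse(hit, L[i, 1:n] + 1L, 0L)
    }
    out <- NULL
    for (i in seq_len(m)) for (j in seq_len(n)) {
        len <- L[i + 1L, j + 1L]
        if (len < minLen) next
        extendable <- i < m && j < n &&
            L[i + 2L, j + 2L] == len + 1L
        if (extendable) next
        out <- rbind(out, data.frame(qstart = i - len + 1L, qend = i,
                                     sstart = j - len + 1L, send = j,
                                     length = len))
    }
    out
}

# full two-library, two-strand oracle; returns the same coordinate
# conventions as findExactMatches (forward-strand subject coordinates)
oracleCommonSubstrings <- function(queries, subjects, minLen) {
    out <- NULL
    for (qi in names(queries)) for (si in names(subjects)) {
        plus <- .oracleMemsOne(queries[[qi]], subjects[[si]], minLen)
        if (!is.null(plus))
            out <- rbind(out, cbind(query_id = qi, subject_id = si,
                                    strand = "+", plus))
        rc <- revcompChr(subjects[[si]])
        minus <- .oracleMemsOne(queries[[qi]], rc, minLen)
        if (!is.null(minus)) {
            sl <- nchar(subjects[[si]])
            tmp <- minus
            tmp$sstart <- sl - minus$send + 1L
            tmp$send <- sl - minus$sstart + 1L
            out <- rbind(out, cbind(query_id = qi, subject_id = si,
                                    strand = "-", tmp))
        }
    }
    if (is.null(out))
        return(data.frame(query_id = character(), subject_id = character(),
                          strand = character(), qstart = integer(),
                          qend = integer(), sstart = integer(),
                          send = integer(), length = integer()))
    out <- out[order(out$query_id, out$subject_id, out$qstart, out$strand,
                     out$sstart), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# full overlap-alignment DP (free end gaps, +1/-2/-4) with traceback;
# returns the same verdict fields as overlapAlign
oracleOverlapAlign <- function(a, b, strand = "+") {
    if (strand == "-") b <- revcompChr(b)
    qa <- strsplit(toupper(a), "")[[1]]
    sa <- strsplit(toupper(b), "")[[1]]
    m <- length(qa); n <- length(sa)
    sc <- function(x, y) if (x == y && x != "N") 1 else -2
    M <- matrix(0, m + 1L, n + 1L)      # free leading gaps
    P <- matrix(0L, m + 1L, n + 1L)     # 1 diag, 2 up, 3 left
    for (i in seq_len(m)) for (j in seq_len(n)) {
        d <- M[i, j] + sc(qa[i], sa[j])
        u <- M[i, j + 1L] - 4
        l <- M[i + 1L, j] - 4
        best <- max(d, u, l)
        M[i + 1L, j + 1L] <- best
        P[i + 1L, j + 1L] <- which.max(c(d, u, l))
    }
    # free trailing gaps: best cell on last row or column
    endCands <- rbind(cbind(m + 1L, seq_len(n + 1L)),
                      cbind(seq_len(m), n + 1L))
    vals <- M[endCands]
    bi <- endCands[which.max(vals), ]
    score <- M[bi[1], bi[2]]
    i <- bi[1]; j <- bi[2]
    nMis <- 0L; nGap <- 0L; cols <- 0L; qspan <- 0L; sspan <- 0L
    while (i > 1L && j > 1L) {
        move <- P[i, j]
        if (move == 1L) {
            if (!(qa[i - 1L] == sa[j - 1L] && qa[i - 1L] != "N"))
                nMis <- nMis + 1L
            qspan <- qspan + 1L; sspan <- sspan + 1L
            i <- i - 1L; j <- j - 1L
        } else if (move == 2L) {
            nGap <- nGap + 1L; qspan <- qspan + 1L
            i <- i - 1L
        } else {
            nGap <- nGap + 1L; sspan <- sspan + 1L
            j <- j - 1L
        }
        cols <- cols + 1L
    }
    flushL <- (i == 1L) || (j == 1L)
    flushR <- (bi[1] == m + 1L) || (bi[2] == n + 1L)
    if (cols == 0L) {
        verdict <- "rejected_nonextension"
        flushL <- FALSE; flushR <- FALSE
    } else {
        verdict <- if (nMis > 0) "rejected_mismatch"
            else if (nGap > 0) "rejected_gap"
            else if (!flushL || !flushR) "rejected_nonextension"
            else "accepted"
    }
    list(score = score, overlap_len = min(qspan, sspan),
         n_mismatch = nMis, n_internal_gap = nGap, flush_left = flushL,
         flush_right = flushR, verdict = verdict)
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracleFisherTwoSided <- function(a, b, c, d) {
    m <- a + b        # row 1 total
    n <- c + d        # row 2 total
    k <- a + c        # column 1 total
    xs <- max(0L, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    pObs <- dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# random contig library for property tests
randomLibrary <- function(id, nContigs, lenRange = c(60, 160)) {
    seqs <- vapply(seq_len(nContigs), function(i)
        rseq(sample(seq.int(lenRange[1], lenRange[2]), 1)), character(1))
    contigLibrary(id, setNames(seqs, paste0(id, "_c", seq_len(nContigs))))
}
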