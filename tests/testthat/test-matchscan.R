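test_that("a sequence matched against itself gives one full-cover plus-strand hit", {
    set.seed(1)
    seqv <- rseq(150)
    hits <- findExactMatches(contigLibrary("A", c(q = seqv)),
                             contigLibrary("B", c(s = seqv)), 100)
    expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
    h <- hits[hits$strand == "+", ]
    expect_equal(c(h$qstart, h$qend, h$sstart, h$send, h$length),
                 c(1L, 150L, 1L, 150L, 150L))
    expect_equal(h$identity, 1)
})

test_that("a planted unique 120-mer is recovered at its exact coordinates", {
    set.seed(2)
    u <- rseq(120)
    # force mismatches at the planted boundaries so the match cannot
    # extend into the flanks by chance
    q <- paste0(rseq(59), "A", u, "G", rseq(59))
    s <- paste0(rseq(59), "C", u, "T", rseq(59))
    qlib <- c(q1 = q)
    slib <- c(s1 = s)
    hits <- findExactMatches(contigLibrary("A", qlib),
                             contigLibrary("B", slib), 100)
    oracle <- oracleCommonSubstrings(qlib, slib, 100)
    expect_equal(nrow(hits), nrow(oracle))
    expect_equal(hits[c("qstart", "qend", "sstart", "send", "length")],
                 oracle[c("qstart", "qend", "sstart", "send", "length")])
    expect_equal(hits$length, 120L)
    expect_equal(c(hits$qstart, hits$sstart), c(61L, 61L))
})

test_that("matches one base below the length threshold are excluded", {
    set.seed(3)
    u <- rseq(99)
    hits <- findExactMatches(
        contigLibrary("A", c(q = paste0(rseq(40), u, rseq(40)))),
        contigLibrary("B", c(s = paste0(rseq(40), u, rseq(40)))), 100)
    expect_equal(nrow(hits), 0L)
    expect_error(findExactMatches(contigLibrary("A", c(q = u)),
                                  contigLibrary("B", c(s = u)), 0),
                 "minLen")
})

test_that("N never participates in an exact match, even against N", {
    left <- strrep("AC", 30)
    right <- strrep("GT", 30)
    withN <- paste0(left, "N", right)
    hits <- findExactMatches(contigLibrary("A", c(q = withN)),
                             contigLibrary("B", c(s = withN)), 30)
    # the N splits what would otherwise be one full-length match
    expect_true(all(hits$length <= 60))
    expect_false(any(hits$qstart <= 60 & hits$qend >= 62 &
                         hits$strand == "+"))
})

test_that("the Karlin-Altschul E-value follows the closed form", {
    p <- scoringParams()
    ka <- karlinAltschulEvalue(100, p, m = 250, n = 6.6e6)
    expect_equal(ka$evalue, 0.46 * 250 * 6.6e6 * exp(-1.28 * 100))
    expect_equal(ka$evalue, 1.95e-47, tolerance = 0.01)
    # one extra score unit scales E by exactly exp(-lambda)
    ka1 <- karlinAltschulEvalue(101, p, m = 250, n = 6.6e6)
    expect_equal(ka1$evalue / ka$evalue, exp(-p@lambda))
    # linear in the database length
    ka2 <- karlinAltschulEvalue(100, p, m = 250, n = 2 * 6.6e6)
    expect_equal(ka2$evalue, 2 * ka$evalue)
    expect_equal(ka$bitscore, (1.28 * 100 - log(0.46)) / log(2))
    expect_error(karlinAltschulEvalue(100, p, m = 0, n = 10), "positive")
})

test_that("filtering keeps sub-threshold hits and counts unique contigs", {
    hits <- data.frame(
        query_id = "q1", subject_id = "s1", strand = "+",
        qstart = c(1L, 10L, 40L), qend = c(120L, 114L, 99L),
        sstart = c(1L, 200L, 400L), send = c(120L, 304L, 459L),
        length = c(120L, 105L, 60L), identity = 1, mismatches = 0L,
        gapopens = 0L, score = c(120, 105, 60), bitscore = 0,
        evalue = c(1e-60, 1e-50, 1e-20))
    res <- filterCandidatePairs(hits, pipelineConfig())
    expect_equal(res$nComparisons, 2L)
    expect_equal(res$nUniqueQuery, 1L)
    expect_equal(res$nUniqueSubject, 1L)
    expect_equal(res$comparisons$length, c(120L, 105L))
    # short perfect hits at the minimum length survive the default E cutoff
    h100 <- hits[1, ]; h100$length <- 100L; h100$score <- 100
    h100$evalue <- karlinAltschulEvalue(100, scoringParams(),
                                        m = 250, n = 1.5e7)$evalue
    expect_equal(filterCandidatePairs(h100,
                                      pipelineConfig())$nComparisons, 1L)
    # ... but not under the decimal reading of the cutoff
    expect_equal(filterCandidatePairs(
        h100, pipelineConfig(evalueNotation = "decimal"))$nComparisons, 0L)
    empty <- filterCandidatePairs(hits[0, ], pipelineConfig())
    expect_equal(empty$nComparisons, 0L)
})

test_that("the scanner equals the brute-force enumeration on random libraries", {
    set.seed(100)
    for (rep in 1:40) {
        minLen <- sample(8:20, 1)
        alphabet <- if (rep %% 3 == 0) c("A", "C") else
            c("A", "C", "G", "T")
        q <- setNames(vapply(1:2, function(i)
            rseq(sample(60:140, 1), alphabet), character(1)),
            paste0("q", 1:2))
        s <- setNames(vapply(1:2, function(i)
            rseq(sample(60:140, 1), alphabet), character(1)),
            paste0("s", 1:2))
        hits <- findExactMatches(contigLibrary("A", q),
                                 contigLibrary("B", s), minLen)
        oracle <- oracleCommonSubstrings(q, s, minLen)
        expect_equal(
            hits[c("query_id", "subject_id", "strand", "qstart", "qend",
                   "sstart", "send", "length")],
            oracle[c("query_id", "subject_id", "strand", "qstart", "qend",
                     "sstart", "send", "length")],
            info = paste("instance", rep))
    }
})

test_that("swapping query and subject roles mirrors the hit set", {
    set.seed(101)
    core <- rseq(40)
    q <- c(q1 = paste0(rseq(20), core, rseq(10)))
    s <- c(s1 = paste0(rseq(5), core, rseq(25)))
    fwd <- findExactMatches(contigLibrary("A", q),
                            contigLibrary("B", s), 30)
    rev <- findExactMatches(contigLibrary("B", s),
                            contigLibrary("A", q), 30)
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(fwd[c("qstart", "qend")],
                 setNames(rev[c("sstart", "send")], c("qstart", "qend")))
})

test_that("raising the length threshold never adds hits", {
    set.seed(102)
    q <- setNames(replicate(3, rseq(120)), paste0("q", 1:3))
    s <- setNames(replicate(3, rseq(120)), paste0("s", 1:3))
    s[1] <- paste0(substr(q[1], 1, 50), rseq(70))
    key <- function(h) paste(h$query_id, h$subject_id, h$strand,
                             h$qstart, h$sstart, h$length)
    h10 <- findExactMatches(contigLibrary("A", q),
                            contigLibrary("B", s), 10)
    h20 <- findExactMatches(contigLibrary("A", q),
                            contigLibrary("B", s), 20)
    expect_true(all(key(h20) %in% key(h10)))
    expect_lte(nrow(h20), nrow(h10))
})
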