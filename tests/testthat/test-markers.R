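test_that("a candidate with no relatives screens clean", {
    set.seed(50)
    libA <- randomLibrary("A", 4, c(200, 250))
    libB <- randomLibrary("B", 4, c(200, 250))
    rep <- uniquenessScreen("A_c1", libA, libB)
    expect_equal(nrow(rep$paralog_hits), 0L)
    L <- nchar(as.character(contigs(libA))[["A_c1"]])
    expect_equal(rep$discriminative_positions, seq_len(L))
    expect_error(uniquenessScreen("ghost", libA, libB), "not found")
})

test_that("a planted 95% paralog is flagged with its substitutions as discriminative", {
    set.seed(51)
    cand <- rseq(250)
    offsets <- seq(40, 220, by = 20)  # 10 sites, 95% identity over 200 bp
    par <- strsplit(substr(cand, 26, 225), "")[[1]]
    parOff <- offsets - 25L
    par[parOff] <- vapply(par[parOff], function(ch)
        sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    libA <- contigLibrary("A", c(cand1 = cand))
    libB <- contigLibrary("B", c(par1 = paste(par, collapse = ""),
                                 other = rseq(200)))
    rep <- uniquenessScreen("cand1", libA, libB)
    expect_true("par1" %in% rep$paralog_hits$contig_id)
    hit <- rep$paralog_hits[rep$paralog_hits$contig_id == "par1", ]
    expect_equal(hit$identity, 0.95, tolerance = 0.01)
    covered <- seq.int(min(hit$qstart), max(hit$qend))
    expect_setequal(intersect(rep$discriminative_positions, covered),
                    offsets)
})

test_that("an unconstrained candidate yields a marker that amplifies itself once", {
    set.seed(52)
    cand <- setNames(rseq(300), "c1")
    mk <- designMarker(cand)
    expect_s4_class(mk, "Marker")
    expect_gte(mk@expectedSize, 100L)
    expect_lte(mk@expectedSize, 450L)
    amp <- insilicoPcr(mk, cand)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$size, mk@expectedSize)
    short <- designMarker(setNames(rseq(60), "tiny"))
    expect_s3_class(short, "designFailure")
    expect_match(short$reason, "too short")
})

test_that("design avoids a paralog using its known polymorphic sites", {
    set.seed(53)
    cand <- rseq(300)
    sites <- c(60, 150, 240)
    par <- strsplit(cand, "")[[1]]
    par[sites] <- vapply(par[sites], function(ch)
        sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    par <- paste(par, collapse = "")
    libA <- contigLibrary("A", c(c1 = cand))
    libB <- contigLibrary("B", c(p1 = par))
    rep <- uniquenessScreen("c1", libA, libB)
    expect_setequal(rep$discriminative_positions, sites)
    mk <- designMarker(setNames(cand, "c1"), rep)
    expect_s4_class(mk, "Marker")
    # the paralog must not amplify; the candidate must
    expect_equal(nrow(insilicoPcr(mk, c(p = par))), 0L)
    expect_equal(nrow(insilicoPcr(mk, c(c = cand))), 1L)
    # at least one chosen 3' window covers a polymorphic site
    w <- pipelineConfig()@pcr3primeExact
    t <- pipelineConfig()@primerTagLen
    fwdWin <- seq(mk@fwdStart + t - w, mk@fwdStart + t - 1)
    revWin <- seq(mk@revEnd - t + 1, mk@revEnd - t + w)
    expect_true(any(sites %in% c(fwdWin, revWin)))
})

test_that("a 3'-terminal mismatch abolishes binding", {
    set.seed(54)
    cand <- setNames(rseq(200), "c1")
    mk <- designMarker(cand)
    t <- nchar(mk@fwdTag)
    tmpl <- strsplit(unname(cand), "")[[1]]
    p <- mk@fwdStart + t - 1L   # fwd tag 3'-terminal base
    tmpl[p] <- setdiff(c("A", "C", "G", "T"), tmpl[p])[1]
    expect_equal(nrow(insilicoPcr(mk, paste(tmpl, collapse = ""))), 0L)
})

test_that("multiple convergent sites yield all in-range amplicons", {
    set.seed(55)
    fwd <- rseq(20); rev <- rseq(20)
    rcRev <- revcompChr(rev)
    tmpl <- paste0(fwd, rseq(80), fwd, rseq(80), rcRev)
    mk <- new("Marker", markerId = "m", sourceCandidate = "x",
              fwdTag = fwd, revTag = rev, fwdStart = 1L, revEnd = 220L,
              expectedSize = 220L)
    amp <- insilicoPcr(mk, c(t1 = tmpl))
    # site math: fwd at 1 and 101, rc(rev) at 201..220
    expect_equal(sort(amp$size), c(120L, 220L))
    expect_equal(sort(amp$start), c(1L, 101L))
})

test_that("a hand-built micro-panel classifies donor-specific and shared markers correctly", {
    set.seed(56)
    donorLocus <- rseq(400)
    recLocus <- local({
        x <- strsplit(donorLocus, "")[[1]]
        idx <- which(runif(400) < 0.05)
        x[idx] <- vapply(x[idx], function(ch)
            sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
        paste(x, collapse = "")
    })
    shared <- rseq(400)
    panel <- list(
        donor = genotypeGenome("donor", "donor",
                               c(l1 = donorLocus, s1 = shared)),
        recurrent = genotypeGenome("recurrent", "recurrent",
                                   c(l1 = recLocus, s1 = shared)),
        bc_apo_1 = genotypeGenome("bc_apo_1", "addition_apo",
                                  c(l1r = recLocus, l1 = donorLocus,
                                    s1 = shared)),
        bc_sex_1 = genotypeGenome("bc_sex_1", "addition_sex",
                                  c(l1 = recLocus, s1 = shared)))
    mk <- designMarker(setNames(donorLocus, "cand"),
                       orthologContext = c(recLocus))
    expect_s4_class(mk, "Marker")
    prof <- screenPanel(mk, panel)
    calls <- setNames(prof$calls$call, prof$calls$genotype_id)
    expect_equal(unname(calls[c("donor", "bc_apo_1")]),
                 c("plus", "plus"))
    expect_equal(unname(calls[c("recurrent", "bc_sex_1")]),
                 c("minus", "minus"))
    expect_equal(classifyLinkage(prof)$call, "carrier_linked")
    # a marker on the shared locus amplifies everything -> uninformative
    mkS <- designMarker(setNames(shared, "sh"))
    profS <- screenPanel(mkS, panel)
    expect_true(all(profS$calls$call == "plus"))
    expect_equal(classifyLinkage(profS)$call, "uninformative")
    bad <- prof$calls
    bad$call[1] <- NA
    expect_error(classifyLinkage(bad), "missing or invalid")
})

test_that("CAPS digestion reports only enzymes with differing fragment multisets", {
    a <- paste0(strrep("A", 100), "GGCC", strrep("G", 196))
    expect_equal(nrow(findCapsPolymorphism(a, a)), 0L)
    b <- paste0(strrep("A", 100), "GACC", strrep("G", 196))
    res <- findCapsPolymorphism(a, b)
    expect_equal(res$enzyme, "HaeIII")
    expect_equal(sort(res$fragments_a[[1]]), c(100L, 200L))
    expect_equal(res$fragments_b[[1]], 300L)
    expect_error(findCapsPolymorphism(a, b,
        data.frame(name = "bad", site = "GGNN")), "A,C,G,T")
})

test_that("digest fragment sizes always sum to the amplicon length", {
    set.seed(57)
    enz <- capsEnzymes()
    for (i in 1:25) {
        amp <- rseq(sample(80:600, 1))
        for (j in seq_len(nrow(enz))) {
            sizes <- alienscan:::.digestSizes(amp, enz$site[j])
            expect_equal(sum(sizes), nchar(amp))
        }
    }
})

test_that("segregation calls follow presence patterns across classes", {
    ids <- paste0("i", 1:22)
    classes <- setNames(rep(c("apo", "sex"), c(10, 12)), ids)
    # allele in 5 apomictic and 7 sexual individuals: 1:1 but unlinked
    pres <- setNames(rep(FALSE, 22), ids)
    pres[c(1:5, 11:17)] <- TRUE
    r <- segregationCheck(pres, classes)
    expect_equal(r$call, "unlinked")
    expect_equal(c(r$n_apo_present, r$n_sex_present), c(5L, 7L))
    # perfect co-segregation with the apomictic class
    pres2 <- setNames(c(rep(TRUE, 10), rep(FALSE, 12)), ids)
    expect_equal(segregationCheck(pres2, classes)$call, "linked")
    # absent everywhere
    pres3 <- setNames(rep(FALSE, 22), ids)
    expect_equal(segregationCheck(pres3, classes)$call, "uninformative")
    expect_error(segregationCheck(pres2[1:10], classes[1:10]),
                 "per class")
})
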