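test_that("an empty design yields empty libraries and an empty truth table", {
    sim <- simulateExperiment(simulationConfig(nGenes = 0, seed = 1))
    expect_equal(length(sim$libraryA), 0L)
    expect_equal(length(sim$libraryB), 0L)
    expect_equal(nrow(sim$truth), 0L)
})

test_that("invalid rates and negative counts are rejected", {
    expect_error(simulationConfig(dSpecies = 1.5), "rates")
    expect_error(simulationConfig(errorRate = -0.1), "rates")
    expect_error(simulationConfig(nGenes = -5))
})

test_that("planted alien transcripts are identical by descent wherever fragments overlap", {
    cfg <- simulationConfig(nGenes = 50, nDonorChromosomes = 1,
                            donorPloidyCopies = 1, expressedFraction = 1,
                            errorRate = 0, seed = 5)
    sim <- simulateExperiment(cfg)
    tr <- sim$truth
    # one copy per library, all expressed: 50 alien records per library
    expect_equal(sum(tr$origin == "alien_ibd"), 100L)
    rownames(tr) <- tr$contig_id
    seqsA <- as.character(contigs(sim$libraryA))
    seqsB <- as.character(contigs(sim$libraryB))
    alienB <- tr[tr$contig_id %in% names(seqsB) &
                     tr$origin == "alien_ibd", ]
    alienA <- tr[tr$contig_id %in% names(seqsA) &
                     tr$origin == "alien_ibd", ]
    for (g in alienA$gene_id) {
        ra <- alienA[alienA$gene_id == g, ]
        rb <- alienB[alienB$gene_id == g, ]
        lo <- max(ra$frag_start, rb$frag_start)
        hi <- min(ra$frag_end, rb$frag_end)
        if (hi < lo) next
        expect_equal(
            substr(seqsA[[ra$contig_id]], lo - ra$frag_start + 1,
                   hi - ra$frag_start + 1),
            substr(seqsB[[rb$contig_id]], lo - rb$frag_start + 1,
                   hi - rb$frag_start + 1),
            info = g)
    }
})

test_that("identical config and seed reproduce byte-identical FASTA output", {
    cfg <- simulationConfig(nGenes = 20, seed = 77)
    s1 <- simulateExperiment(cfg)
    s2 <- simulateExperiment(cfg)
    f1 <- withr::local_tempfile(fileext = ".fasta")
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeContigs(s1$libraryA, f1)
    writeContigs(s2$libraryA, f2)
    expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    expect_identical(s1$truth, s2$truth)
    expect_identical(as.character(contigs(s1$libraryB)),
                     as.character(contigs(s2$libraryB)))
})

test_that("every contig appears exactly once in the truth table", {
    sim <- simulateExperiment(simulationConfig(nGenes = 30, seed = 8))
    ids <- c(names(contigs(sim$libraryA)), names(contigs(sim$libraryB)))
    expect_setequal(sim$truth$contig_id, ids)
    expect_equal(anyDuplicated(sim$truth$contig_id), 0L)
})

test_that("donor-recurrent ortholog divergence tracks the configured rate", {
    d <- 0.05
    sim <- simulateExperiment(simulationConfig(nGenes = 40, seed = 21,
                                               dSpecies = d))
    donor <- sim$panel$donor@sequences
    rec <- sim$panel$recurrent@sequences
    diffs <- 0L; sites <- 0L
    for (g in sprintf("g%03d", 1:40)) {
        a <- strsplit(as.character(donor[[paste0(g, ".c1")]]), "")[[1]]
        b <- strsplit(as.character(rec[[paste0(g, ".rp")]]), "")[[1]]
        diffs <- diffs + sum(a != b)
        sites <- sites + length(a)
    }
    # two independent branches at d/2 each; coincident hits deflate
    # the observed distance to d - d^2/3
    expected <- d - d^2 / 3
    expect_equal(diffs / sites, expected, tolerance = 0.08)
})

test_that("panel genomes follow the crossing design", {
    sim <- simulateExperiment(simulationConfig(nGenes = 30, seed = 9))
    classes <- vapply(sim$panel, function(g) g@classLabel, character(1))
    expect_equal(sum(classes == "addition_apo"), 4L)
    expect_equal(sum(classes == "addition_sex"), 4L)
    expect_equal(sum(classes == "f1_apo"), 10L)
    expect_equal(sum(classes == "f1_sex"), 12L)
    alienLoci <- grep("\\.c1$",
                      names(sim$panel$bc_apo_1@sequences), value = TRUE)
    expect_gt(length(alienLoci), 0)
    expect_false(any(grepl("\\.c1$",
                           names(sim$panel$bc_sex_1@sequences))))
    asgrLoci <- paste0(sim$asgrGenes, ".c1")
    expect_true(all(asgrLoci %in% names(sim$panel$f1_apo_1@sequences)))
    expect_false(any(asgrLoci %in% names(sim$panel$f1_sex_1@sequences)))
})

test_that("with no 3' bias fragment starts are uniform", {
    set.seed(30)
    cfg <- simulationConfig(threePrimeBias = 0, fragMeanLen = 250,
                            fragLenSd = 0)
    fr <- fragmentTranscript(1000, cfg, n = 10000)
    # fixed length 250 -> starts uniform on 1..751
    h <- table(cut(fr$start, breaks = seq(0.5, 751.5, length.out = 11)))
    p <- chisq.test(as.vector(h))$p.value
    expect_gt(p, 0.01)
})

test_that("positive bias shifts fragment mass toward the 3' end", {
    set.seed(31)
    cfg <- simulationConfig(threePrimeBias = 1.5)
    fr <- fragmentTranscript(1000, cfg, n = 3000)
    expect_gt(mean((fr$start + fr$end) / 2), 500)
    # transcripts below the minimum fragment length yield no fragments
    expect_equal(nrow(fragmentTranscript(50, cfg, n = 10)), 0L)
})

test_that("3'-half coverage under bias matches the numeric integral of the density", {
    set.seed(32)
    beta <- 2; T <- 500; f <- 150
    cfg <- simulationConfig(threePrimeBias = beta, fragMeanLen = f,
                            fragLenSd = 0, fragMinLen = 120L)
    fr <- fragmentTranscript(T, cfg, n = 20000)
    ovl <- pmax(0, pmin(fr$end, T) - pmax(fr$start, T / 2 + 1) + 1)
    empirical <- mean(ovl) / f
    s <- seq_len(T - f + 1)
    w <- exp(beta * s / T)
    ovlS <- pmax(0, pmin(s + f - 1, T) - pmax(s, T / 2 + 1) + 1)
    expected <- sum(w * ovlS) / (sum(w) * f)
    expect_equal(empirical, expected, tolerance = 0.01)
})

test_that("the identical-stretch rate among ortholog contig pairs matches a Monte-Carlo mutation-placement oracle", {
    cfg <- simulationConfig(nGenes = 200, dSpecies = 0.05, seed = 1)
    sim <- simulateExperiment(cfg)
    tr <- sim$truth
    rownames(tr) <- tr$contig_id
    seqsA <- as.character(contigs(sim$libraryA))
    seqsB <- as.character(contigs(sim$libraryB))
    a1 <- tr[tr$contig_id %in% names(seqsA) & tr$copy_id == "c1", ]
    bR <- tr[tr$origin == "recurrent", ]
    common <- intersect(a1$gene_id, bR$gene_id)
    minRun <- 100L
    hasRun <- function(x) {
        r <- rle(x)
        any(r$values & r$lengths >= minRun)
    }
    obs <- c(); pOracle <- c()
    d <- 0.05
    set.seed(2)
    for (g in common) {
        ra <- a1[a1$gene_id == g, ][1, ]
        rb <- bR[bR$gene_id == g, ][1, ]
        lo <- max(ra$frag_start, rb$frag_start)
        hi <- min(ra$frag_end, rb$frag_end)
        L <- hi - lo + 1L
        if (L < minRun) next
        sa <- strsplit(substr(seqsA[[ra$contig_id]],
                              lo - ra$frag_start + 1,
                              hi - ra$frag_start + 1), "")[[1]]
        sb <- strsplit(substr(seqsB[[rb$contig_id]],
                              lo - rb$frag_start + 1,
                              hi - rb$frag_start + 1), "")[[1]]
        obs <- c(obs, hasRun(sa == sb))
        # oracle: place mutations on two branches at d/2 per site; a site
        # differs unless both branches hit it and land on the same base
        reps <- 150
        hit <- vapply(seq_len(reps), function(r) {
            mA <- runif(L) < d / 2
            mB <- runif(L) < d / 2
            differ <- (mA != mB) | (mA & mB & runif(L) < 2 / 3)
            hasRun(!differ)
        }, logical(1))
        pOracle <- c(pOracle, mean(hit))
    }
    expect_gt(length(obs), 30)
    se <- sqrt(sum(pOracle * (1 - pOracle))) / length(pOracle) + 0.02
    expect_lt(abs(mean(obs) - mean(pOracle)), 4 * se + 0.02)
})
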