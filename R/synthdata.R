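## Synthetic addition-line experiment: donor / recurrent-parent /
## addition-line transcriptomes with planted identity-by-descent, genotype
## panel genomes, and a ground-truth table.

.dnaBases <- c("A", "C", "G", "T")

.randSeqChars <- function(n) sample(.dnaBases, n, replace = TRUE)

# Bernoulli substitutions at `rate` per site, each to a uniformly chosen
# different base.
.mutateChars <- function(x, rate) {
    if (rate <= 0 || !length(x)) return(x)
    idx <- which(runif(length(x)) < rate)
    if (!length(idx)) return(x)
    code <- match(x[idx], .dnaBases) - 1L
    x[idx] <- .dnaBases[((code + sample(1:3, length(idx),
                                        replace = TRUE)) %% 4L) + 1L]
    x
}

#' Sample 3'-biased fragment intervals from a transcript
#'
#' Fragment lengths are normal with mean `fragMeanLen` and sd `fragLenSd`,
#' clamped to `[fragMinLen, min(fragMaxLen, transcriptLen)]`. The fragment start is drawn
#' with probability proportional to `exp(beta * s / T)` (equivalently,
#' exponential down-weighting by the distance of the fragment's 3' end from
#' the transcript 3' end), so `beta = 0` gives uniform starts and larger
#' `beta` shifts mass toward the 3' end, emulating the 3' bias of
#' amplified-RNA libraries.
#'
#' @param transcriptLen transcript length, bp.
#' @param config a [SimulationConfig-class] (fragment model and beta).
#' @param n number of fragments to draw.
#' @return A data.frame with columns `start`, `end` (1-based inclusive);
#'   zero rows when the transcript is shorter than the minimum fragment.
#' @examples
#' fragmentTranscript(500, simulationConfig(threePrimeBias = 2), n = 3)
#' @export
fragmentTranscript <- function(transcriptLen, config = simulationConfig(),
                               n = 1L) {
    T <- as.integer(transcriptLen)
    if (T < config@fragMinLen)
        return(data.frame(start = integer(), end = integer()))
    f <- as.integer(round(rnorm(n, config@fragMeanLen, config@fragLenSd)))
    f <- pmin(pmax(f, config@fragMinLen), config@fragMaxLen, T)
    beta <- config@threePrimeBias
    # weight over starts s: exp(-beta * (T - (s + f - 1)) / T) propto
    # exp(beta * s / T), independent of f
    w <- exp(beta * seq_len(T) / T)
    start <- vapply(f, function(fi) {
        smax <- T - fi + 1L
        if (smax == 1L) 1L
        else sample.int(smax, 1L, prob = w[seq_len(smax)])
    }, integer(1))
    data.frame(start = start, end = start + f - 1L)
}

#' Simulate a chromosome-addition transcriptome experiment
#'
#' Generates the full synthetic design under one RNG seed: ancestral genes
#' with optional introns on `nDonorChromosomes` chromosome groups; a donor
#' lineage with `donorPloidyCopies` homeologous haplotypes per gene
#' (haplotype 1 is the reference haplotype, further copies diverge by
#' `dHomeolog`); a recurrent parent and a third relative each diverged from
#' the ancestor so that donor-recurrent ortholog divergence is `dSpecies`;
#' an addition line carrying the recurrent transcriptome plus the alien
#' chromosome's haplotype-1 transcripts copied identical by descent.
#' Contig libraries are 3'-biased transcript fragments (library A: donor,
#' all copies; library B: addition line), and a genotype panel of
#' intron-bearing genomic templates is produced for in-silico PCR: donor,
#' recurrent, relative, apomictic/sexual backcross segregants and
#' apomictic/sexual F1s, with the apospory-specific region (ASGR) modelled
#' as a flagged subset of alien-chromosome genes present in apomictic but
#' not sexual F1s.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `libraryA`, `libraryB`
#'   ([ContigLibrary-class]), `panel` (named list of
#'   [GenotypeGenome-class]), `truth` (data.frame with contig_id, origin,
#'   gene_id, chromosome_id, copy_id, frag_start, frag_end), `asgrGenes`
#'   (gene ids flagged ASGR) and `config`.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 10, seed = 42))
#' table(sim$truth$origin)
#' @export
simulateExperiment <- function(config = simulationConfig()) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    set.seed(config@seed)
    libIdA <- "DP"   # donor parent
    libIdB <- "AL"   # addition line
    emptyTruth <- data.frame(contig_id = character(), origin = character(),
                             gene_id = character(),
                             chromosome_id = character(),
                             copy_id = character(), frag_start = integer(),
                             frag_end = integer())
    if (config@nGenes == 0L) {
        empty <- Biostrings::DNAStringSet()
        return(list(libraryA = contigLibrary(libIdA, empty),
                    libraryB = contigLibrary(libIdB, empty),
                    panel = list(), truth = emptyTruth,
                    asgrGenes = character(), config = config))
    }

    nG <- config@nGenes
    K <- config@nDonorChromosomes
    C <- config@donorPloidyCopies
    geneIds <- sprintf("g%03d", seq_len(nG))
    chrGrp <- rep_len(seq_len(K), nG)
    chrLab <- paste0("chr", chrGrp)
    alienGenes <- geneIds[chrLab == config@alienChromosomeId]
    nAsgr <- if (length(alienGenes) && config@asgrFraction > 0)
        max(1L, as.integer(round(config@asgrFraction * length(alienGenes))))
    else 0L
    asgrGenes <- sort(sample(alienGenes, min(nAsgr, length(alienGenes))))

    lo <- config@transcriptLenRange[1]
    hi <- config@transcriptLenRange[2]
    iLo <- config@intronLenRange[1]
    iHi <- config@intronLenRange[2]

    donorTx <- vector("list", nG)      # [[gene]][[copy]] transcript chars
    recTx <- vector("list", nG)
    donorGenomic <- vector("list", nG)
    recGenomic <- character(nG)
    relGenomic <- character(nG)

    for (g in seq_len(nG)) {
        Tlen <- sample(seq.int(lo, hi), 1L)
        anc <- .randSeqChars(Tlen)
        nInt <- rbinom(1L, 2L, config@intronProb)
        exonMask <- rep(TRUE, Tlen)
        ancG <- anc
        if (nInt > 0 && Tlen > 4) {
            at <- sort(sample(seq.int(2L, Tlen - 2L), nInt))
            pieces <- list()
            mask <- list()
            prev <- 0L
            for (ii in seq_len(nInt)) {
                pieces[[2 * ii - 1]] <- anc[(prev + 1L):at[ii]]
                mask[[2 * ii - 1]] <- rep(TRUE, at[ii] - prev)
                ilen <- sample(seq.int(iLo, iHi), 1L)
                pieces[[2 * ii]] <- .randSeqChars(ilen)
                mask[[2 * ii]] <- rep(FALSE, ilen)
                prev <- at[ii]
            }
            pieces[[2 * nInt + 1]] <- anc[(prev + 1L):Tlen]
            mask[[2 * nInt + 1]] <- rep(TRUE, Tlen - prev)
            ancG <- unlist(pieces)
            exonMask <- unlist(mask)
        }
        donorBase <- .mutateChars(ancG, config@dSpecies / 2)
        recHap <- .mutateChars(ancG, config@dSpecies / 2)
        relHap <- .mutateChars(ancG, config@dSpecies / 2)
        copies <- vector("list", C)
        copies[[1]] <- donorBase
        if (C > 1)
            for (cc in 2:C)
                copies[[cc]] <- .mutateChars(donorBase, config@dHomeolog)
        donorGenomic[[g]] <- vapply(copies, paste, character(1),
                                    collapse = "")
        recGenomic[g] <- paste(recHap, collapse = "")
        relGenomic[g] <- paste(relHap, collapse = "")
        donorTx[[g]] <- lapply(copies, function(x) x[exonMask])
        recTx[[g]] <- recHap[exonMask]
    }

    emitted <- new.env(parent = emptyenv())
    emitted$seqs <- character()
    emitted$truth <- list()
    emit <- function(lib, tx, origin, gene, chrom, copy) {
        frag <- fragmentTranscript(length(tx), config, n = 1L)
        if (!nrow(frag)) return(invisible(NULL))
        piece <- .mutateChars(tx[frag$start:frag$end], config@errorRate)
        id <- paste0(lib, "_c", length(emitted$seqs) + 1L)
        emitted$seqs[[id]] <- paste(piece, collapse = "")
        emitted$truth[[id]] <- data.frame(
            contig_id = id, origin = origin, gene_id = gene,
            chromosome_id = chrom, copy_id = copy,
            frag_start = frag$start, frag_end = frag$end)
        invisible(NULL)
    }

    # library A: donor parent, all homeologous copies
    for (g in seq_len(nG)) {
        for (cc in seq_len(C)) {
            if (runif(1) < config@expressedFraction) {
                origin <- if (chrLab[g] == config@alienChromosomeId &&
                              cc == 1L) "alien_ibd" else "donor_non_alien"
                emit(libIdA, donorTx[[g]][[cc]], origin, geneIds[g],
                     paste0(chrLab[g], ".", cc), paste0("c", cc))
            }
        }
    }
    nA <- length(emitted$seqs)

    # library B: addition line = recurrent transcriptome + alien chromosome
    # haplotype-1 transcripts (identical by descent with the donor)
    for (g in seq_len(nG)) {
        if (runif(1) < config@expressedFraction)
            emit(libIdB, recTx[[g]], "recurrent", geneIds[g],
                 paste0("rp_", chrLab[g]), "rp")
        if (chrLab[g] == config@alienChromosomeId &&
            runif(1) < config@expressedFraction)
            emit(libIdB, donorTx[[g]][[1]], "alien_ibd", geneIds[g],
                 paste0(chrLab[g], ".1"), "c1")
    }

    allSeqs <- emitted$seqs
    truth <- do.call(rbind, emitted$truth)
    rownames(truth) <- NULL
    counts <- rpois(length(allSeqs), 27) + 1L
    isA <- seq_along(allSeqs) <= nA
    libraryA <- contigLibrary(libIdA, allSeqs[isA], counts[isA])
    libraryB <- contigLibrary(libIdB, allSeqs[!isA], counts[!isA])

    # panel genomes (genomic, intron-bearing templates)
    donorLoci <- unlist(lapply(seq_len(nG), function(g)
        setNames(donorGenomic[[g]],
                 paste0(geneIds[g], ".c", seq_len(C)))))
    recLoci <- setNames(recGenomic, paste0(geneIds, ".rp"))
    relLoci <- setNames(relGenomic, paste0(geneIds, ".rel"))
    hap1Loci <- setNames(vapply(donorGenomic, `[`, character(1), 1L),
                         paste0(geneIds, ".c1"))
    alienHap1 <- hap1Loci[paste0(alienGenes, ".c1")]
    f1SexLoci <- hap1Loci[!geneIds %in% asgrGenes]

    panel <- list(
        donor = genotypeGenome("donor", "donor", donorLoci),
        recurrent = genotypeGenome("recurrent", "recurrent", recLoci),
        relative = genotypeGenome("relative", "relative", relLoci))
    addGeno <- function(prefix, classLabel, count, seqs) {
        for (i in seq_len(count)) {
            id <- paste0(prefix, "_", i)
            panel[[id]] <<- genotypeGenome(id, classLabel, seqs)
        }
    }
    spec <- config@panelSpec
    addGeno("bc_apo", "addition_apo", spec[["bc_apo"]],
            c(recLoci, alienHap1))
    addGeno("bc_sex", "addition_sex", spec[["bc_sex"]], recLoci)
    addGeno("f1_apo", "f1_apo", spec[["f1_apo"]], c(recLoci, hap1Loci))
    addGeno("f1_sex", "f1_sex", spec[["f1_sex"]], c(recLoci, f1SexLoci))

    list(libraryA = libraryA, libraryB = libraryB, panel = panel,
         truth = truth, asgrGenes = asgrGenes, config = config)
}

#' Write the outputs of a simulated experiment to disk
#'
#' Emits the two contig libraries as FASTA (70-column wrap), the truth
#' table as TSV, each panel genome as a multi-FASTA, and the configuration
#' as JSON, so a simulation is fully reproducible from its directory.
#'
#' @param sim the list returned by [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeContigs(sim$libraryA,
                 file.path(dir, paste0(libraryId(sim$libraryA), ".fasta")))
    writeContigs(sim$libraryB,
                 file.path(dir, paste0(libraryId(sim$libraryB), ".fasta")))
    write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pdir <- file.path(dir, "panel")
    dir.create(pdir, showWarnings = FALSE)
    for (gg in sim$panel)
        Biostrings::writeXStringSet(
            gg@sequences,
            file.path(pdir, paste0(gg@genotypeId, ".fasta")), width = 70L)
    cfg <- sim$config
    cfgList <- lapply(setNames(slotNames(cfg), slotNames(cfg)),
                      function(s) methods::slot(cfg, s))
    jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
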