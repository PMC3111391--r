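#' @include alienscan-package.R
NULL

## ---------------------------------------------------------------- classes

#' Karlin-Altschul scoring parameters for ungapped nucleotide matches
#'
#' Holds the match/mismatch scores and the Karlin-Altschul parameters
#' (lambda, K) used to convert an ungapped alignment score into an E-value
#' \eqn{E = K m n e^{-\lambda S}}. The defaults are the standard BLASTN
#' values for +1/-2 scoring.
#'
#' @slot reward positive score per matching base (default +1).
#' @slot penalty negative score per mismatching base (default -2).
#' @slot lambda Karlin-Altschul lambda, in nats per score unit (default 1.28).
#' @slot K Karlin-Altschul K constant (default 0.46).
#' @export
setClass("ScoringParams",
    representation(reward = "numeric", penalty = "numeric",
                   lambda = "numeric", K = "numeric"),
    prototype(reward = 1, penalty = -2, lambda = 1.28, K = 0.46))

setValidity("ScoringParams", function(object) {
    msg <- character()
    if (length(object@reward) != 1 || object@reward <= 0)
        msg <- c(msg, "reward must be a single positive number")
    if (length(object@penalty) != 1 || object@penalty >= 0)
        msg <- c(msg, "penalty must be a single negative number")
    if (length(object@lambda) != 1 || object@lambda <= 0)
        msg <- c(msg, "lambda must be positive")
    if (length(object@K) != 1 || object@K <= 0)
        msg <- c(msg, "K must be positive")
    if (length(msg)) msg else TRUE
})

#' @param reward,penalty,lambda,K see slot documentation.
#' @return A `ScoringParams` object.
#' @rdname ScoringParams-class
#' @export
scoringParams <- function(reward = 1, penalty = -2, lambda = 1.28, K = 0.46) {
    new("ScoringParams", reward = reward, penalty = penalty,
        lambda = lambda, K = K)
}

#' Pipeline thresholds and marker-design parameters
#'
#' Central configuration for the detection funnel. The primary E-value
#' threshold applies to the exact-match scan (candidate identification), the
#' uniqueness threshold to the within-transcriptome paralog screen. The
#' published protocol prints its cutoffs as "e^-100" and "e^-25"; by default
#' these are read as powers of the natural base (exp(-100), exp(-25)), the
#' reading under which perfect matches of the minimum length pass the
#' primary filter. Set `evalueNotation = "decimal"` for the 1e-100 / 1e-25
#' reading.
#'
#' @slot minExactLen minimum exact-match / overlap length in bp (default 100).
#' @slot minIdentity minimum identity fraction for candidates (default 1.0).
#' @slot eThresholdPrimary E-value cutoff for the candidate scan.
#' @slot eThresholdUniqueness E-value cutoff for the paralog screen.
#' @slot scoring a [ScoringParams-class] object.
#' @slot ampliconSizeRange allowed expected amplicon size on the transcript
#'   template, bp (default 100-450).
#' @slot primerTagLen primer tag length in bp (default 20).
#' @slot pcr3primeExact number of 3'-terminal tag bases that must match a
#'   template exactly for binding (default 15).
#' @slot pcrMaxMismatch maximum mismatches tolerated in the rest of the tag
#'   (default 2).
#' @slot pcrSizeRange size window for a reported in-silico amplicon, bp
#'   (default 50-2000; wider than `ampliconSizeRange` because genomic
#'   templates carry introns).
#' @slot fdrLevel false discovery rate for the term-count comparison
#'   (default 0.01).
#' @export
setClass("PipelineConfig",
    representation(minExactLen = "integer", minIdentity = "numeric",
                   eThresholdPrimary = "numeric",
                   eThresholdUniqueness = "numeric",
                   scoring = "ScoringParams",
                   ampliconSizeRange = "numeric", primerTagLen = "integer",
                   pcr3primeExact = "integer", pcrMaxMismatch = "integer",
                   pcrSizeRange = "numeric", fdrLevel = "numeric"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@minExactLen < 1) msg <- c(msg, "minExactLen must be >= 1")
    if (object@minIdentity <= 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must be in (0, 1]")
    if (object@eThresholdPrimary <= 0 || object@eThresholdUniqueness <= 0)
        msg <- c(msg, "E-value thresholds must be positive")
    if (length(object@ampliconSizeRange) != 2 ||
        diff(object@ampliconSizeRange) < 0 || object@ampliconSizeRange[1] <= 0)
        msg <- c(msg, "ampliconSizeRange must be an increasing positive pair")
    if (length(object@pcrSizeRange) != 2 || diff(object@pcrSizeRange) < 0)
        msg <- c(msg, "pcrSizeRange must be an increasing pair")
    if (object@primerTagLen < object@pcr3primeExact)
        msg <- c(msg, "primerTagLen must be >= pcr3primeExact")
    if (object@fdrLevel <= 0 || object@fdrLevel >= 1)
        msg <- c(msg, "fdrLevel must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param minExactLen,minIdentity,ampliconSizeRange,primerTagLen see slots.
#' @param pcr3primeExact,pcrMaxMismatch,pcrSizeRange,fdrLevel,scoring see slots.
#' @param eThresholdPrimary,eThresholdUniqueness explicit E-value cutoffs;
#'   when `NULL` they are derived from `evalueNotation`.
#' @param evalueNotation `"natural"` (default) reads the protocol cutoffs
#'   e^-100 / e^-25 with the natural base; `"decimal"` as 1e-100 / 1e-25.
#' @return A `PipelineConfig` object.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(minExactLen = 100L, minIdentity = 1.0,
                           eThresholdPrimary = NULL,
                           eThresholdUniqueness = NULL,
                           evalueNotation = c("natural", "decimal"),
                           scoring = scoringParams(),
                           ampliconSizeRange = c(100, 450),
                           primerTagLen = 20L, pcr3primeExact = 15L,
                           pcrMaxMismatch = 2L, pcrSizeRange = c(50, 2000),
                           fdrLevel = 0.01) {
    evalueNotation <- match.arg(evalueNotation)
    if (is.null(eThresholdPrimary))
        eThresholdPrimary <- if (evalueNotation == "natural")
            exp(-100) else 1e-100
    if (is.null(eThresholdUniqueness))
        eThresholdUniqueness <- if (evalueNotation == "natural")
            exp(-25) else 1e-25
    new("PipelineConfig", minExactLen = as.integer(minExactLen),
        minIdentity = minIdentity, eThresholdPrimary = eThresholdPrimary,
        eThresholdUniqueness = eThresholdUniqueness, scoring = scoring,
        ampliconSizeRange = as.numeric(ampliconSizeRange),
        primerTagLen = as.integer(primerTagLen),
        pcr3primeExact = as.integer(pcr3primeExact),
        pcrMaxMismatch = as.integer(pcrMaxMismatch),
        pcrSizeRange = as.numeric(pcrSizeRange), fdrLevel = fdrLevel)
}

#' A library of assembled transcript contigs
#'
#' One assembled contig library (one genotype's transcriptome), the unit of
#' all downstream comparisons. Wraps a [Biostrings::DNAStringSet] whose
#' names are the contig identifiers, with an optional per-contig read count
#' parsed from assembly headers.
#'
#' @slot libraryId single-string library identifier.
#' @slot contigs named `DNAStringSet`, upper case, alphabet ACGTN.
#' @slot readCounts integer vector parallel to `contigs` (NA if unknown).
#' @export
setClass("ContigLibrary",
    representation(libraryId = "character", contigs = "DNAStringSet",
                   readCounts = "integer"))

setValidity("ContigLibrary", function(object) {
    msg <- character()
    ids <- names(object@contigs)
    if (length(object@libraryId) != 1 || !nzchar(object@libraryId))
        msg <- c(msg, "libraryId must be a non-empty string")
    if (length(object@contigs)) {
        if (is.null(ids) || any(!nzchar(ids)))
            msg <- c(msg, "all contigs must be named")
        else if (anyDuplicated(ids))
            msg <- c(msg, "contig ids must be unique within a library")
        if (any(Biostrings::width(object@contigs) == 0))
            msg <- c(msg, "contig sequences must be non-empty")
    }
    if (length(object@readCounts) != length(object@contigs))
        msg <- c(msg, "readCounts must be parallel to contigs")
    if (length(msg)) msg else TRUE
})

#' @param libraryId,contigs,readCounts see slot documentation; `contigs` may
#'   be a named character vector or a `DNAStringSet`.
#' @return A `ContigLibrary` object.
#' @rdname ContigLibrary-class
#' @export
contigLibrary <- function(libraryId, contigs,
                          readCounts = rep(NA_integer_, length(contigs))) {
    if (!methods::is(contigs, "DNAStringSet"))
        contigs <- Biostrings::DNAStringSet(toupper(contigs))
    new("ContigLibrary", libraryId = libraryId, contigs = contigs,
        readCounts = as.integer(readCounts))
}

#' One genotype's genome for in-silico PCR screening
#'
#' A set of (intron-bearing) genomic locus templates for one individual of
#' the mapping panel, labelled by its role in the crossing design.
#'
#' @slot genotypeId individual identifier.
#' @slot classLabel one of `donor`, `recurrent`, `relative`, `addition_apo`,
#'   `addition_sex`, `f1_apo`, `f1_sex`.
#' @slot sequences named `DNAStringSet` of genomic locus templates.
#' @export
setClass("GenotypeGenome",
    representation(genotypeId = "character", classLabel = "character",
                   sequences = "DNAStringSet"))

.panelClasses <- c("donor", "recurrent", "relative", "addition_apo",
                   "addition_sex", "f1_apo", "f1_sex")

setValidity("GenotypeGenome", function(object) {
    msg <- character()
    if (!object@classLabel %in% .panelClasses)
        msg <- c(msg, paste("classLabel must be one of:",
                            paste(.panelClasses, collapse = ", ")))
    if (length(object@genotypeId) != 1 || !nzchar(object@genotypeId))
        msg <- c(msg, "genotypeId must be a non-empty string")
    if (length(msg)) msg else TRUE
})

#' @param genotypeId,classLabel,sequences see slot documentation.
#' @return A `GenotypeGenome` object.
#' @rdname GenotypeGenome-class
#' @export
genotypeGenome <- function(genotypeId, classLabel, sequences) {
    if (!methods::is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    new("GenotypeGenome", genotypeId = genotypeId, classLabel = classLabel,
        sequences = sequences)
}

#' A chromosome-specific PCR marker
#'
#' A primer-tag pair designed on a verified candidate contig, the in-silico
#' analogue of a SCAR marker. Tag coordinates are 1-based positions on the
#' candidate: the forward tag covers `fwdStart .. fwdStart+len-1`, the
#' reverse tag is the reverse complement of the candidate window ending at
#' `revEnd`.
#'
#' @slot markerId marker identifier.
#' @slot sourceCandidate identifier of the candidate contig.
#' @slot fwdTag,revTag tag sequences, 5' to 3'.
#' @slot fwdStart,revEnd tag coordinates on the candidate.
#' @slot expectedSize expected amplicon size on the transcript template, bp.
#' @export
setClass("Marker",
    representation(markerId = "character", sourceCandidate = "character",
                   fwdTag = "character", revTag = "character",
                   fwdStart = "integer", revEnd = "integer",
                   expectedSize = "integer"))

setValidity("Marker", function(object) {
    msg <- character()
    if (object@expectedSize != object@revEnd - object@fwdStart + 1L)
        msg <- c(msg, "expectedSize must equal revEnd - fwdStart + 1")
    if (nchar(object@fwdTag) != nchar(object@revTag))
        msg <- c(msg, "tags must have equal length")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic addition-line experiment
#'
#' Defines the simulated crossing design: a high-ploidy donor transcriptome
#' with diverged homeologous gene copies, a recurrent parent diverged at the
#' species level, and an addition line carrying the recurrent genome plus
#' one donor chromosome whose transcripts are copied identical by descent.
#' Contigs are short 3'-biased transcript fragments; genotype-panel genomes
#' carry intron-bearing templates for in-silico PCR.
#'
#' @slot nGenes number of ancestral genes.
#' @slot nDonorChromosomes number of donor chromosome groups; genes are
#'   assigned round-robin.
#' @slot alienChromosomeId chromosome group transmitted to the addition
#'   line, e.g. `"chr1"`.
#' @slot donorPloidyCopies homeologous copies per gene in the donor.
#' @slot dHomeolog substitutions/site between donor haplotype 1 and each
#'   other homeologous copy.
#' @slot dSpecies substitutions/site between donor and recurrent orthologs.
#' @slot transcriptLenRange min/max ancestral transcript length, bp.
#' @slot fragMeanLen,fragLenSd,fragMinLen,fragMaxLen contig (fragment)
#'   length model, bp; lengths are clamped into
#'   `[fragMinLen, min(fragMaxLen, transcript length)]`, matching the
#'   length range of verifiable assembled contigs.
#' @slot threePrimeBias exponential 3'-bias rate beta (0 = uniform starts).
#' @slot errorRate substitutions/site added to emitted contigs.
#' @slot expressedFraction probability that a locus yields a contig in a
#'   given library.
#' @slot intronProb per-slot probability of an intron (two slots per gene).
#' @slot intronLenRange intron length range, bp.
#' @slot panelSpec named integer vector with elements `bc_apo`, `bc_sex`,
#'   `f1_apo`, `f1_sex`: panel sizes for the backcross segregants and F1s.
#' @slot asgrFraction fraction of alien-chromosome genes flagged as part of
#'   the apospory-specific genomic region (ASGR).
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @export
setClass("SimulationConfig",
    representation(nGenes = "integer", nDonorChromosomes = "integer",
                   alienChromosomeId = "character",
                   donorPloidyCopies = "integer",
                   dHomeolog = "numeric", dSpecies = "numeric",
                   transcriptLenRange = "numeric",
                   fragMeanLen = "numeric", fragLenSd = "numeric",
                   fragMinLen = "integer", fragMaxLen = "integer",
                   threePrimeBias = "numeric",
                   errorRate = "numeric", expressedFraction = "numeric",
                   intronProb = "numeric", intronLenRange = "numeric",
                   panelSpec = "integer", asgrFraction = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    rates <- c(dHomeolog = object@dHomeolog, dSpecies = object@dSpecies,
               errorRate = object@errorRate,
               expressedFraction = object@expressedFraction,
               intronProb = object@intronProb,
               asgrFraction = object@asgrFraction)
    bad <- rates < 0 | rates > 1
    if (any(bad))
        msg <- c(msg, paste("rates must be in [0, 1]:",
                            paste(names(rates)[bad], collapse = ", ")))
    if (object@nGenes < 0) msg <- c(msg, "nGenes must be >= 0")
    if (object@nDonorChromosomes < 1)
        msg <- c(msg, "nDonorChromosomes must be >= 1")
    if (object@donorPloidyCopies < 1)
        msg <- c(msg, "donorPloidyCopies must be >= 1")
    if (object@fragMeanLen <= 0) msg <- c(msg, "fragMeanLen must be > 0")
    if (object@fragMinLen > object@fragMaxLen)
        msg <- c(msg, "fragMinLen must be <= fragMaxLen")
    if (length(object@transcriptLenRange) != 2 ||
        diff(object@transcriptLenRange) < 0)
        msg <- c(msg, "transcriptLenRange must be an increasing pair")
    if (!all(c("bc_apo", "bc_sex", "f1_apo", "f1_sex") %in%
             names(object@panelSpec)))
        msg <- c(msg, "panelSpec needs bc_apo, bc_sex, f1_apo, f1_sex")
    else if (any(object@panelSpec < 0))
        msg <- c(msg, "panel sizes must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param nGenes,nDonorChromosomes,alienChromosomeId,donorPloidyCopies see slots.
#' @param dHomeolog,dSpecies,transcriptLenRange,fragMeanLen,fragLenSd see slots.
#' @param fragMinLen,fragMaxLen,threePrimeBias,errorRate,expressedFraction see slots.
#' @param intronProb,intronLenRange,panelSpec,asgrFraction,seed see slots.
#' @return A `SimulationConfig` object.
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(nGenes = 60L, nDonorChromosomes = 7L,
                             alienChromosomeId = "chr1",
                             donorPloidyCopies = 4L,
                             dHomeolog = 0.02, dSpecies = 0.05,
                             transcriptLenRange = c(300, 900),
                             fragMeanLen = 250, fragLenSd = 60,
                             fragMinLen = 180L, fragMaxLen = 450L,
                             threePrimeBias = 1.5,
                             errorRate = 0, expressedFraction = 0.7,
                             intronProb = 0.5, intronLenRange = c(80, 500),
                             panelSpec = c(bc_apo = 4L, bc_sex = 4L,
                                           f1_apo = 10L, f1_sex = 12L),
                             asgrFraction = 0.25, seed = 1L) {
    if (any(c(nGenes, nDonorChromosomes, donorPloidyCopies) < 0))
        stop("counts must be non-negative")
    new("SimulationConfig", nGenes = as.integer(nGenes),
        nDonorChromosomes = as.integer(nDonorChromosomes),
        alienChromosomeId = alienChromosomeId,
        donorPloidyCopies = as.integer(donorPloidyCopies),
        dHomeolog = dHomeolog, dSpecies = dSpecies,
        transcriptLenRange = as.numeric(transcriptLenRange),
        fragMeanLen = fragMeanLen, fragLenSd = fragLenSd,
        fragMinLen = as.integer(fragMinLen),
        fragMaxLen = as.integer(fragMaxLen),
        threePrimeBias = threePrimeBias, errorRate = errorRate,
        expressedFraction = expressedFraction, intronProb = intronProb,
        intronLenRange = as.numeric(intronLenRange),
        panelSpec = setNames(as.integer(panelSpec), names(panelSpec)),
        asgrFraction = asgrFraction, seed = as.integer(seed))
}

## ------------------------------------------------------------- accessors

#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @describeIn ContigLibrary-class library identifier.
#' @param x a `ContigLibrary`.
#' @export
setMethod("libraryId", "ContigLibrary", function(x) x@libraryId)

#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @describeIn ContigLibrary-class the underlying `DNAStringSet`.
#' @export
setMethod("contigs", "ContigLibrary", function(x) x@contigs)

#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @describeIn ContigLibrary-class per-contig read counts (NA if unknown).
#' @export
setMethod("readCounts", "ContigLibrary",
          function(x) setNames(x@readCounts, names(x@contigs)))

#' @describeIn ContigLibrary-class number of contigs.
#' @export
setMethod("length", "ContigLibrary", function(x) length(x@contigs))

setMethod("show", "ContigLibrary", function(object) {
    w <- Biostrings::width(object@contigs)
    cat("ContigLibrary '", object@libraryId, "': ",
        length(object@contigs), " contigs", sep = "")
    if (length(w))
        cat(", width ", min(w), "-", max(w), " (mean ",
            round(mean(w), 1), ")", sep = "")
    cat("\n")
})

setMethod("show", "GenotypeGenome", function(object) {
    cat("GenotypeGenome '", object@genotypeId, "' [", object@classLabel,
        "]: ", length(object@sequences), " locus templates\n", sep = "")
})

setMethod("show", "Marker", function(object) {
    cat("Marker '", object@markerId, "' on ", object@sourceCandidate,
        ": ", object@fwdTag, " / ", object@revTag,
        " expected ", object@expectedSize, " bp\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes on",
        object@nDonorChromosomes, "chromosome groups,",
        object@donorPloidyCopies, "donor copies; alien =",
        object@alienChromosomeId, "\n")
    cat("  dHomeolog =", object@dHomeolog, " dSpecies =", object@dSpecies,
        " errorRate =", object@errorRate, " seed =", object@seed, "\n")
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig: minExactLen =", object@minExactLen,
        " minIdentity =", object@minIdentity, "\n")
    cat("  E thresholds:", format(object@eThresholdPrimary, digits = 3),
        "(primary)", format(object@eThresholdUniqueness, digits = 3),
        "(uniqueness)\n")
})
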