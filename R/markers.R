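## Marker stage: within-transcriptome uniqueness screening, discriminative
## primer-tag design, in-silico PCR across a genotype panel, CAPS digest
## polymorphisms, and the linkage rule engine.

.seedLen <- 16L  # exact seed for the uniqueness (paralog) screen

# Ungapped X-drop extension of an exact seed through mismatches, +1/-2.
.extendSeed <- function(qc, sc, qs, qe, ss, se, reward, penalty,
                        xdrop = 12) {
    score <- (qe - qs + 1L) * reward
    best <- score; bq <- qe; bs <- se
    i <- qe + 1L; j <- se + 1L
    while (i <= length(qc) && j <= length(sc)) {
        score <- score + if (qc[i] == sc[j] && qc[i] != "N") reward
            else penalty
        if (score > best) { best <- score; bq <- i; bs <- j }
        if (best - score > xdrop) break
        i <- i + 1L; j <- j + 1L
    }
    qe <- bq; se <- bs
    score <- best; bq0 <- qs; bs0 <- ss
    i <- qs - 1L; j <- ss - 1L
    while (i >= 1L && j >= 1L) {
        score <- score + if (qc[i] == sc[j] && qc[i] != "N") reward
            else penalty
        if (score > best) { best <- score; bq0 <- i; bs0 <- j }
        if (best - score > xdrop) break
        i <- i - 1L; j <- j - 1L
    }
    qs <- bq0; ss <- bs0
    len <- qe - qs + 1L
    nmatch <- sum(qc[qs:qe] == sc[ss:se] & qc[qs:qe] != "N")
    list(qstart = qs, qend = qe, sstart = ss, send = se, length = len,
         matches = nmatch, mismatches = len - nmatch,
         score = nmatch * reward + (len - nmatch) * penalty)
}

#' Estimate the uniqueness of a candidate within both transcriptomes
#'
#' Local similarity search of the candidate against both contig libraries
#' (16 bp exact seeds, ungapped X-drop extension under the configured
#' match/mismatch scores), excluding the candidate itself and its verified
#' partner. Hits with Karlin-Altschul E-value at most
#' `eThresholdUniqueness` are reported as paralog hits; the discriminative
#' positions are the candidate positions that differ from (or are not
#' covered by) every reported hit -- the positions marker design can
#' exploit.
#'
#' @param candidateId id of the candidate contig.
#' @param libraryA,libraryB the two [ContigLibrary-class] objects; the
#'   candidate must be present in one of them.
#' @param config a [PipelineConfig-class].
#' @param exclude contig ids to leave out of the search (the candidate
#'   itself is always excluded; pass its verified partner here).
#' @return A list with `candidate_id`, `paralog_hits` (data.frame:
#'   contig_id, library_id, strand, qstart, qend, sstart, send,
#'   aligned_len, identity, score, evalue), `paralog_seqs` (named character
#'   of the hit contig sequences, for downstream specificity checks) and
#'   `discriminative_positions` (integer vector of candidate offsets).
#' @export
uniquenessScreen <- function(candidateId, libraryA, libraryB,
                             config = pipelineConfig(),
                             exclude = character()) {
    seqsA <- contigs(libraryA)
    seqsB <- contigs(libraryB)
    cand <- if (candidateId %in% names(seqsA)) seqsA[[candidateId]]
        else if (candidateId %in% names(seqsB)) seqsB[[candidateId]]
        else stop("candidate ", candidateId, " not found in either library")
    candChars <- strsplit(as.character(cand), "")[[1]]
    L <- length(candChars)

    subjects <- c(setNames(as.character(seqsA),
                           paste0("A\r", names(seqsA))),
                  setNames(as.character(seqsB),
                           paste0("B\r", names(seqsB))))
    drop <- sub("^[AB]\r", "", names(subjects)) %in%
        c(candidateId, exclude)
    subjects <- subjects[!drop]
    nTotal <- sum(nchar(subjects))
    disc <- rep(TRUE, L)
    hitsOut <- list()
    if (length(subjects) && L >= .seedLen) {
        rcSubjects <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(subjects)))
        reward <- config@scoring@reward
        penalty <- config@scoring@penalty
        for (strand in c("+", "-")) {
            subj <- if (strand == "+") subjects else rcSubjects
            seeds <- mem_scan_cpp(as.character(cand), unname(subj),
                                  .seedLen)
            if (!nrow(seeds)) next
            for (si in unique(seeds$sidx)) {
                schars <- strsplit(subj[[si]], "")[[1]]
                rows <- seeds[seeds$sidx == si, , drop = FALSE]
                best <- NULL
                for (r in seq_len(nrow(rows))) {
                    h <- .extendSeed(candChars, schars, rows$qstart[r],
                                     rows$qstart[r] + rows$length[r] - 1L,
                                     rows$sstart[r],
                                     rows$sstart[r] + rows$length[r] - 1L,
                                     reward, penalty)
                    if (is.null(best) || h$score > best$score) best <- h
                }
                ev <- karlinAltschulEvalue(best$score, config@scoring,
                                           m = L, n = nTotal)$evalue
                if (ev > config@eThresholdUniqueness) next
                sid <- strsplit(names(subj)[si], "\r")[[1]]
                hitsOut[[length(hitsOut) + 1L]] <- data.frame(
                    contig_id = sid[2],
                    library_id = if (sid[1] == "A") libraryId(libraryA)
                        else libraryId(libraryB),
                    strand = strand, qstart = best$qstart,
                    qend = best$qend, sstart = best$sstart,
                    send = best$send, aligned_len = best$length,
                    identity = best$matches / best$length,
                    score = best$score, evalue = ev)
                rng <- best$qstart:best$qend
                same <- candChars[rng] ==
                    schars[best$sstart:best$send] & candChars[rng] != "N"
                disc[rng][same] <- FALSE
            }
        }
    }
    paralogs <- if (length(hitsOut)) do.call(rbind, hitsOut)
        else data.frame(contig_id = character(), library_id = character(),
                        strand = character(), qstart = integer(),
                        qend = integer(), sstart = integer(),
                        send = integer(), aligned_len = integer(),
                        identity = numeric(), score = numeric(),
                        evalue = numeric())
    parSeqs <- character()
    if (nrow(paralogs)) {
        uniq <- unique(paralogs$contig_id)
        parSeqs <- setNames(vapply(uniq, function(id) {
            if (id %in% names(seqsA)) as.character(seqsA[[id]])
            else as.character(seqsB[[id]])
        }, character(1)), uniq)
    }
    list(candidate_id = candidateId, paralog_hits = paralogs,
         paralog_seqs = parSeqs,
         discriminative_positions = which(disc))
}

# Candidate positions that are covered by a similar region of the subject
# set (16 bp exact seeds, ungapped X-drop extension) and differ from every
# such region -- the positions that actively abolish binding. Positions
# with no context coverage are reported FALSE: nothing binds there, so
# they confer no ranking preference.
.discAgainst <- function(candChars, subjectStrings, config) {
    L <- length(candChars)
    disc <- rep(TRUE, L)
    covered <- rep(FALSE, L)
    if (!length(subjectStrings) || L < .seedLen) return(disc & covered)
    cand <- paste(candChars, collapse = "")
    rcSubjects <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(subjectStrings)))
    reward <- config@scoring@reward
    penalty <- config@scoring@penalty
    for (strand in 1:2) {
        subj <- if (strand == 1) subjectStrings else rcSubjects
        seeds <- mem_scan_cpp(cand, unname(subj), .seedLen)
        if (!nrow(seeds)) next
        for (si in unique(seeds$sidx)) {
            schars <- strsplit(subj[[si]], "")[[1]]
            rows <- seeds[seeds$sidx == si, , drop = FALSE]
            for (r in seq_len(nrow(rows))) {
                h <- .extendSeed(candChars, schars, rows$qstart[r],
                                 rows$qstart[r] + rows$length[r] - 1L,
                                 rows$sstart[r],
                                 rows$sstart[r] + rows$length[r] - 1L,
                                 reward, penalty)
                rng <- h$qstart:h$qend
                covered[rng] <- TRUE
                same <- candChars[rng] == schars[h$sstart:h$send] &
                    candChars[rng] != "N"
                disc[rng][same] <- FALSE
            }
        }
    }
    disc & covered
}

#' Design a discriminative marker on a candidate contig
#'
#' Places a forward and a reverse primer tag of `primerTagLen` bases on the
#' candidate so that the expected amplicon size falls in
#' `ampliconSizeRange`, ranking placements by how many discriminative
#' positions (positions distinguishing the candidate from its paralogs)
#' their 3'-terminal `pcr3primeExact` windows cover. Specificity is then
#' enforced by in-silico PCR: a placement is accepted only when
#' [insilicoPcr()] yields no amplicon from the context sequences -- the
#' supplied `orthologContext` when given, otherwise the paralog hit
#' contigs from the uniqueness report. Returns a design failure (not an
#' error) when no placement qualifies.
#'
#' @param candidate a single named character (name = contig id), or a
#'   length-1 named `DNAStringSet`.
#' @param report optional result of [uniquenessScreen()] for the candidate.
#' @param orthologContext optional `DNAStringSet`/character of sequences
#'   the marker must not amplify (e.g. the recurrent parent's templates).
#' @param positiveContext optional `DNAStringSet`/character of sequences
#'   the marker must amplify (e.g. the donor's genomic templates); rules
#'   out tags spanning exon junctions that would fail on genomic DNA.
#' @param config a [PipelineConfig-class].
#' @param markerId identifier for the marker (default derived from the
#'   candidate id).
#' @return A [Marker-class], or an object of class `"designFailure"` with a
#'   `$reason` element.
#' @export
designMarker <- function(candidate, report = NULL, orthologContext = NULL,
                         positiveContext = NULL, config = pipelineConfig(),
                         markerId = NULL) {
    if (methods::is(candidate, "DNAStringSet"))
        candidate <- setNames(as.character(candidate), names(candidate))
    candId <- names(candidate)[1]
    if (is.null(candId)) stop("candidate must be named with its contig id")
    seqStr <- toupper(unname(candidate[1]))
    L <- nchar(seqStr)
    t <- config@primerTagLen
    w <- config@pcr3primeExact
    minAmp <- max(config@ampliconSizeRange[1], 2 * t)
    maxAmp <- min(config@ampliconSizeRange[2], L)
    if (is.null(markerId)) markerId <- paste0("mk_", candId)
    fail <- function(reason)
        structure(list(candidate_id = candId, reason = reason),
                  class = "designFailure")
    if (L < minAmp)
        return(fail(sprintf(
            "candidate too short (%d bp) for the minimum amplicon (%d bp)",
            L, as.integer(minAmp))))

    disc <- rep(TRUE, L)
    havePar <- FALSE
    if (!is.null(report)) {
        disc <- seq_len(L) %in% report$discriminative_positions
        havePar <- nrow(report$paralog_hits) > 0
    }

    # specificity context: sequences the marker must not amplify; when no
    # explicit context is given, the paralog hits themselves stand in
    ctxIn <- orthologContext
    if (is.null(ctxIn) && havePar && length(report$paralog_seqs))
        ctxIn <- report$paralog_seqs
    context <- NULL
    if (!is.null(ctxIn)) {
        context <- if (methods::is(ctxIn, "DNAStringSet")) ctxIn
        else Biostrings::DNAStringSet(toupper(ctxIn))
    }
    positive <- NULL
    if (!is.null(positiveContext)) {
        positive <- if (methods::is(positiveContext, "DNAStringSet"))
            positiveContext
        else Biostrings::DNAStringSet(toupper(positiveContext))
    }

    # positions that differ from every similar region of the context are
    # what actually confers specificity; rank placements by those first,
    # then by discriminative positions from the uniqueness report
    candChars <- strsplit(seqStr, "")[[1]]
    ctxDisc <- if (!is.null(context) && length(context))
        .discAgainst(candChars, unique(as.character(context)), config)
    else rep(FALSE, L)

    winScore <- function(mask) {
        cum <- cumsum(c(0L, as.integer(mask)))
        ws <- function(from, to) cum[to + 1L] - cum[from]
        list(f = vapply(seq_len(L - t + 1L),
                        function(i) ws(i + t - w, i + t - 1L), integer(1)),
             r = vapply(seq.int(t, L),
                        function(j) ws(j - t + 1L, j - t + w), integer(1)))
    }
    sc1 <- winScore(ctxDisc)
    sc2 <- winScore(disc)
    cand <- expand.grid(i = seq_len(L - t + 1L), j = seq.int(t, L))
    cand$size <- cand$j - cand$i + 1L
    cand <- cand[cand$size >= minAmp & cand$size <= maxAmp, , drop = FALSE]
    if (!nrow(cand)) return(fail("no tag placement fits the size range"))
    jIdx <- cand$j - t + 1L
    # prefer placements where each tag's 3' window covers a
    # context-discriminative site, then maximize coverage
    ctxBoth <- pmin(sc1$f[cand$i], sc1$r[jIdx]) > 0L
    ctxTotal <- sc1$f[cand$i] + sc1$r[jIdx]
    repTotal <- sc2$f[cand$i] + sc2$r[jIdx]
    # deterministic scatter as the final tie-break so equal-score attempts
    # probe different regions of the candidate
    scatter <- ((cand$i - 1L) %/% 8L * 5L + (cand$j - 1L) %/% 8L * 3L) %% 7L
    cand <- cand[order(-ctxBoth, -ctxTotal, -repTotal, scatter, cand$i,
                       -cand$j), , drop = FALSE]
    nTry <- min(nrow(cand), 60L)
    for (k in seq_len(nTry)) {
        i <- cand$i[k]; j <- cand$j[k]
        fwdTag <- substr(seqStr, i, i + t - 1L)
        revTag <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(seqStr, j - t + 1L, j))))
        mk <- new("Marker", markerId = markerId, sourceCandidate = candId,
                  fwdTag = fwdTag, revTag = revTag,
                  fwdStart = as.integer(i), revEnd = as.integer(j),
                  expectedSize = as.integer(j - i + 1L))
        if (!is.null(context) && length(context) &&
            nrow(insilicoPcr(mk, context, config)) > 0) next
        if (!is.null(positive) && length(positive) &&
            nrow(insilicoPcr(mk, positive, config)) == 0) next
        return(mk)
    }
    fail("no specific placement found (all tested placements amplify the context)")
}

# Binding sites of a tag on the plus strand of one template string.
# direction "right": the tag reads along the plus strand (primer extends
# rightward); "left": the template contains the tag's reverse complement
# (primer extends leftward). Returns start positions of the matched window.
.tagSites <- function(tag, templates, templateChar, config,
                      direction = c("right", "left")) {
    direction <- match.arg(direction)
    t <- nchar(tag)
    w <- config@pcr3primeExact
    pat <- if (direction == "right") tag
        else as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(tag)))
    m <- Biostrings::vmatchPattern(pat, templates,
                                   max.mismatch = config@pcrMaxMismatch,
                                   fixed = TRUE)
    lapply(seq_along(templates), function(i) {
        st <- IRanges::start(m[[i]])
        if (!length(st)) return(integer())
        en <- st + t - 1L
        keep <- if (direction == "right")
            substring(templateChar[i], en - w + 1L, en) ==
                substr(tag, t - w + 1L, t)
        else
            substring(templateChar[i], st, st + w - 1L) ==
                substr(pat, 1L, w)
        st[keep]
    })
}

#' Enumerate in-silico PCR amplicons of a marker on a template
#'
#' A tag binds a template site iff its 3'-terminal `pcr3primeExact` bases
#' match exactly and at most `pcrMaxMismatch` mismatches occur in the
#' remainder of the tag. An amplicon is reported for every convergent pair
#' of binding sites (one rightward, one leftward, on either assignment of
#' the two tags) whose span falls within `pcrSizeRange`.
#'
#' @param marker a [Marker-class].
#' @param template a [GenotypeGenome-class], `DNAStringSet`, or named
#'   character vector of template sequences.
#' @param config a [PipelineConfig-class].
#' @return A data.frame with columns template_id, start, end, size,
#'   orientation (`"FR"` if the forward tag is the rightward primer).
#' @export
insilicoPcr <- function(marker, template, config = pipelineConfig()) {
    seqs <- if (methods::is(template, "GenotypeGenome")) template@sequences
        else if (methods::is(template, "DNAStringSet")) template
        else Biostrings::DNAStringSet(toupper(template))
    empty <- data.frame(template_id = character(), start = integer(),
                        end = integer(), size = integer(),
                        orientation = character())
    if (!length(seqs)) return(empty)
    if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
    chars <- as.character(seqs)
    t <- config@primerTagLen
    lo <- config@pcrSizeRange[1]
    hi <- config@pcrSizeRange[2]
    sites <- list(
        fwdR = .tagSites(marker@fwdTag, seqs, chars, config, "right"),
        fwdL = .tagSites(marker@fwdTag, seqs, chars, config, "left"),
        revR = .tagSites(marker@revTag, seqs, chars, config, "right"),
        revL = .tagSites(marker@revTag, seqs, chars, config, "left"))
    out <- list()
    for (i in seq_along(seqs)) {
        for (ori in c("FR", "RF")) {
            right <- if (ori == "FR") sites$fwdR[[i]] else sites$revR[[i]]
            left <- if (ori == "FR") sites$revL[[i]] else sites$fwdL[[i]]
            if (!length(right) || !length(left)) next
            combos <- expand.grid(a = right, b = left)
            combos$size <- combos$b + t - combos$a
            keep <- combos$b >= combos$a & combos$size >= lo &
                combos$size <= hi
            combos <- combos[keep, , drop = FALSE]
            if (!nrow(combos)) next
            out[[length(out) + 1L]] <- data.frame(
                template_id = names(seqs)[i], start = combos$a,
                end = combos$b + t - 1L, size = combos$size,
                orientation = ori)
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    res <- res[order(res$template_id, res$start, res$end,
                     res$orientation), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Screen a marker across a genotype panel
#'
#' Runs [insilicoPcr()] on every genome of the panel and records a plus
#' call (one or more amplicons), a minus call (none), or fail (empty
#' genome) for each genotype.
#'
#' @param marker a [Marker-class].
#' @param panel named list of [GenotypeGenome-class] objects.
#' @param config a [PipelineConfig-class].
#' @return A list with `marker_id` and `calls`, a data.frame with columns
#'   genotype_id, class_label, call, n_amplicons, sizes (comma-separated).
#' @export
screenPanel <- function(marker, panel, config = pipelineConfig()) {
    if (!length(panel)) stop("panel must be non-empty")
    # segregants of one class often share a genome; reuse their screens
    cacheKeys <- list()
    cacheVals <- list()
    rows <- lapply(panel, function(gg) {
        if (!length(gg@sequences))
            return(data.frame(genotype_id = gg@genotypeId,
                              class_label = gg@classLabel, call = "fail",
                              n_amplicons = 0L, sizes = ""))
        chars <- as.character(gg@sequences)
        hit <- 0L
        for (k in seq_along(cacheKeys))
            if (identical(cacheKeys[[k]], chars)) { hit <- k; break }
        if (hit) {
            amp <- cacheVals[[hit]]
        } else {
            amp <- insilicoPcr(marker, gg, config)
            cacheKeys[[length(cacheKeys) + 1L]] <<- chars
            cacheVals[[length(cacheVals) + 1L]] <<- amp
        }
        data.frame(genotype_id = gg@genotypeId,
                   class_label = gg@classLabel,
                   call = if (nrow(amp)) "plus" else "minus",
                   n_amplicons = nrow(amp),
                   sizes = paste(sort(amp$size), collapse = ","))
    })
    calls <- do.call(rbind, rows)
    rownames(calls) <- NULL
    list(marker_id = marker@markerId, calls = calls)
}

#' Classify a marker's linkage from its panel amplification profile
#'
#' Encodes the mapping decision rules: a marker is linked to the alien
#' (carrier) chromosome iff it amplifies the donor and every apomictic
#' addition segregant but neither the recurrent parent nor any sexual
#' addition segregant; it is additionally tightly linked to the ASGR iff it
#' amplifies every apomictic F1 and no sexual F1. A marker amplifying the
#' recurrent parent (or nothing at all) is uninformative; a marker that
#' fails the carrier criteria in any other way is unlinked.
#'
#' @param profile result of [screenPanel()] (or its `calls` data.frame).
#' @return A list with `marker_id`, `call` (one of `carrier_linked`,
#'   `asgr_tight`, `unlinked`, `uninformative`) and `evidence`, a
#'   data.frame of plus counts per panel class.
#' @export
classifyLinkage <- function(profile) {
    calls <- if (is.data.frame(profile)) profile else profile$calls
    markerId <- if (is.data.frame(profile)) NA_character_
        else profile$marker_id
    if (any(is.na(calls$call)) ||
        !all(calls$call %in% c("plus", "minus", "fail")))
        stop("profile contains missing or invalid calls")
    plus <- calls$call == "plus"
    minus <- calls$call == "minus"
    cls <- calls$class_label
    evidence <- do.call(rbind, lapply(intersect(.panelClasses,
                                                unique(cls)), function(k)
        data.frame(class = k, n_plus = sum(plus[cls == k]),
                   n_total = sum(cls == k))))
    allPlus <- function(k) any(cls == k) && all(plus[cls == k])
    allMinus <- function(k) any(cls == k) && all(minus[cls == k])
    call <- if (any(plus[cls == "recurrent"]) || !any(plus))
        "uninformative"
    else if (allPlus("donor") && allPlus("addition_apo") &&
             allMinus("recurrent") && allMinus("addition_sex")) {
        if (allPlus("f1_apo") && allMinus("f1_sex")) "asgr_tight"
        else "carrier_linked"
    } else "unlinked"
    list(marker_id = markerId, call = call, evidence = evidence)
}

#' Default CAPS enzyme panel
#'
#' @return A data.frame with columns `name` and `site`.
#' @export
capsEnzymes <- function() {
    data.frame(name = c("HaeIII", "HpyCH4IV"),
               site = c("GGCC", "ACGT"))
}

.digestSizes <- function(seq, site) {
    L <- nchar(seq)
    pos <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
    pos <- pos[pos > 0]
    # fragment boundary at the recognition-site start
    cuts <- sort(unique(pos - 1L))
    cuts <- cuts[cuts > 0 & cuts < L]
    diff(c(0L, cuts, L))
}

#' Find CAPS polymorphisms between two amplicons
#'
#' Digests both amplicons at every occurrence of each enzyme's recognition
#' site (fragment boundaries at the site start) and reports the enzymes
#' whose fragment-size multisets differ -- a cleaved amplified polymorphic
#' sequence (CAPS) marker.
#'
#' @param ampliconA,ampliconB amplicon sequences (character or DNAString).
#' @param enzymes a data.frame with columns `name` and `site` over ACGT;
#'   default [capsEnzymes()].
#' @return A data.frame with one row per polymorphic enzyme: `enzyme`,
#'   `fragments_a`, `fragments_b` (list columns of fragment sizes).
#' @examples
#' findCapsPolymorphism(
#'   paste0(strrep("A", 100), "GGCC", strrep("T", 196)),
#'   paste0(strrep("A", 100), "GACC", strrep("T", 196)))
#' @export
findCapsPolymorphism <- function(ampliconA, ampliconB,
                                 enzymes = capsEnzymes()) {
    a <- toupper(as.character(ampliconA))
    b <- toupper(as.character(ampliconB))
    if (!nzchar(a) || !nzchar(b)) stop("amplicons must be non-empty")
    if (any(grepl("[^ACGT]", enzymes$site)))
        stop("recognition sites must be over {A,C,G,T}")
    rows <- lapply(seq_len(nrow(enzymes)), function(i) {
        fa <- sort(.digestSizes(a, enzymes$site[i]))
        fb <- sort(.digestSizes(b, enzymes$site[i]))
        if (length(fa) == length(fb) && all(fa == fb)) return(NULL)
        data.frame(enzyme = enzymes$name[i], fragments_a = I(list(fa)),
                   fragments_b = I(list(fb)))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(enzyme = character(),
                          fragments_a = I(list()),
                          fragments_b = I(list())))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Test co-segregation of a marker allele with the apomictic class
#'
#' Given allele presence/absence across a segregating population and the
#' reproductive class of each individual, calls the marker `linked` when
#' presence perfectly co-segregates with the apomictic class, `unlinked`
#' when the allele occurs in at least one individual of each class, and
#' `uninformative` otherwise (e.g. absent everywhere).
#'
#' @param presence named logical vector (individual -> allele present).
#' @param classes named vector with values `"apo"` / `"sex"`, same
#'   individuals as `presence`.
#' @return A list: `call`, `n_apo_present`, `n_sex_present`, `n_apo`,
#'   `n_sex`.
#' @examples
#' segregationCheck(
#'   setNames(c(TRUE, TRUE, FALSE, FALSE), paste0("i", 1:4)),
#'   setNames(c("apo", "apo", "sex", "sex"), paste0("i", 1:4)))
#' @export
segregationCheck <- function(presence, classes) {
    if (!all(names(presence) %in% names(classes)))
        stop("every individual needs a class assignment")
    classes <- classes[names(presence)]
    if (!all(classes %in% c("apo", "sex")))
        stop("classes must be 'apo' or 'sex'")
    apo <- classes == "apo"
    if (!any(apo) || !any(!apo))
        stop("need at least one individual per class")
    nApoP <- sum(presence[apo])
    nSexP <- sum(presence[!apo])
    call <- if (nApoP == 0 && nSexP == 0) "uninformative"
        else if (nApoP >= 1 && nSexP >= 1) "unlinked"
        else if (nApoP == sum(apo) && nSexP == 0) "linked"
        else "uninformative"
    list(call = call, n_apo_present = nApoP, n_sex_present = nSexP,
         n_apo = sum(apo), n_sex = sum(!apo))
}
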