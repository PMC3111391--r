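## Orchestration: simulate/load -> scan -> filter -> verify -> summarize ->
## uniqueness -> design -> panel screen -> classify, with a run manifest
## and plain-file artifacts so any stage can be re-run standalone.

.md5Of <- function(object) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(object, tf)
    unname(tools::md5sum(tf))
}

#' Run the full alien-transcript detection funnel
#'
#' Executes every stage in order on either a synthetic experiment (pass a
#' [SimulationConfig-class] or the result of [simulateExperiment()]) or a
#' pair of FASTA paths. Marker stages (uniqueness screen, design, panel
#' screen, linkage classification) run only when panel genomes are
#' available. Stage outputs are returned in one list together with a run
#' manifest carrying the funnel counts; with `outDir` set, per-stage
#' TSV/FASTA/JSON artifacts are written as well.
#'
#' For each verified pair the query contig is the marker-design candidate;
#' its verified partner is excluded from the uniqueness screen, and the
#' recurrent-parent and sexual-segregant genomes serve as the
#' non-amplification context for specificity, mirroring the screening
#' order of the wet protocol.
#'
#' @param input a [SimulationConfig-class], the list returned by
#'   [simulateExperiment()], a list with elements `libraryA`, `libraryB`
#'   (and optional `panel`, `truth`), or a character vector of two FASTA
#'   paths (query library, subject library).
#' @param config a [PipelineConfig-class].
#' @param outDir optional directory for stage artifacts.
#' @return A list with elements `libraryA`, `libraryB`, `panel`, `truth`,
#'   `hits`, `candidates` (from [filterCandidatePairs()]), `alignments`,
#'   `accepted`, `summary`, `markers` (data.frame), `profiles` (long
#'   data.frame of panel calls), `linkage` (data.frame), and `manifest`.
#' @export
runAll <- function(input, config = pipelineConfig(), outDir = NULL) {
    if (methods::is(input, "SimulationConfig"))
        input <- simulateExperiment(input)
    if (is.character(input)) {
        if (length(input) != 2)
            stop("expected two FASTA paths (query, subject)")
        input <- list(libraryA = readContigs(input[1]),
                      libraryB = readContigs(input[2]))
    }
    libA <- input$libraryA
    libB <- input$libraryB
    panel <- input$panel
    truth <- input$truth

    hits <- findExactMatches(libA, libB, config@minExactLen,
                             config@scoring)
    candidates <- filterCandidatePairs(hits, config)
    alignments <- verifyComparisons(candidates, libA, libB)
    accepted <- alignments[alignments$verdict == "accepted", , drop = FALSE]
    summary <- summarizeCandidates(alignments, libA, libB)

    markers <- data.frame(marker_id = character(), candidate = character(),
                          partner = character(), fwd_tag = character(),
                          rev_tag = character(), expected_size = integer(),
                          status = character())
    profiles <- data.frame(marker_id = character(),
                           genotype_id = character(),
                           class_label = character(), call = character(),
                           n_amplicons = integer(), sizes = character())
    linkage <- data.frame(marker_id = character(), candidate = character(),
                          call = character())
    if (!is.null(panel) && length(panel) && nrow(accepted)) {
        classes <- vapply(panel, function(g) g@classLabel, character(1))
        ctxSeqs <- unlist(lapply(panel[classes %in%
                                       c("recurrent", "addition_sex")],
                                 function(g) as.character(g@sequences)))
        context <- if (length(ctxSeqs))
            Biostrings::DNAStringSet(unique(unname(ctxSeqs))) else NULL
        posSeqs <- unlist(lapply(panel[classes == "donor"],
                                 function(g) as.character(g@sequences)))
        positive <- if (length(posSeqs))
            Biostrings::DNAStringSet(unique(unname(posSeqs))) else NULL
        aSeq <- as.character(contigs(libA))
        for (i in seq_len(nrow(accepted))) {
            candId <- accepted$query_id[i]
            partner <- accepted$subject_id[i]
            report <- uniquenessScreen(candId, libA, libB, config,
                                       exclude = partner)
            mk <- designMarker(setNames(aSeq[candId], candId), report,
                               orthologContext = context,
                               positiveContext = positive, config = config)
            if (inherits(mk, "designFailure")) {
                markers <- rbind(markers, data.frame(
                    marker_id = NA_character_, candidate = candId,
                    partner = partner, fwd_tag = NA_character_,
                    rev_tag = NA_character_, expected_size = NA_integer_,
                    status = mk$reason))
                next
            }
            markers <- rbind(markers, data.frame(
                marker_id = mk@markerId, candidate = candId,
                partner = partner, fwd_tag = mk@fwdTag,
                rev_tag = mk@revTag, expected_size = mk@expectedSize,
                status = "designed"))
            prof <- screenPanel(mk, panel, config)
            profiles <- rbind(profiles,
                              cbind(marker_id = mk@markerId, prof$calls))
            cl <- classifyLinkage(prof)
            linkage <- rbind(linkage, data.frame(
                marker_id = mk@markerId, candidate = candId,
                call = cl$call))
        }
    }

    manifest <- list(
        config_hash = .md5Of(config),
        inputs = list(library_a = libraryId(libA),
                      library_b = libraryId(libB),
                      n_panel_genomes = length(panel)),
        counts = list(
            n_query_contigs = length(libA),
            n_subject_contigs = length(libB),
            n_exact_matches = nrow(hits),
            n_comparisons = candidates$nComparisons,
            n_unique_query = candidates$nUniqueQuery,
            n_unique_subject = candidates$nUniqueSubject,
            n_pairs_aligned = nrow(alignments),
            n_verified_pairs = nrow(accepted),
            mean_overlap_bp = summary$mean_overlap_bp,
            min_overlap_bp = summary$min_overlap,
            max_overlap_bp = summary$max_overlap,
            n_markers_designed = sum(markers$status == "designed"),
            linkage_calls = as.list(table(linkage$call))),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    manifest$report <- c(
        sprintf("libraries: %d query vs %d subject contigs",
                length(libA), length(libB)),
        sprintf("comparisons (>= %d bp, identity >= %.2f, E <= %.3g): %d",
                config@minExactLen, config@minIdentity,
                config@eThresholdPrimary, candidates$nComparisons),
        sprintf("unique contigs: %d query, %d subject",
                candidates$nUniqueQuery, candidates$nUniqueSubject),
        sprintf("verified inter-genotype contigs (no mismatches): %d",
                nrow(accepted)),
        if (nrow(accepted)) sprintf(
            "overlap: mean %s bp (range %s-%s bp)",
            summary$mean_overlap_bp, summary$min_overlap,
            summary$max_overlap) else NULL,
        sprintf("markers designed: %d; linkage calls: %s",
                sum(markers$status == "designed"),
                if (nrow(linkage)) paste(names(table(linkage$call)),
                                         as.integer(table(linkage$call)),
                                         sep = "=", collapse = ", ")
                else "none"))

    result <- list(libraryA = libA, libraryB = libB, panel = panel,
                   truth = truth, hits = hits, candidates = candidates,
                   alignments = alignments, accepted = accepted,
                   summary = summary, markers = markers,
                   profiles = profiles, linkage = linkage,
                   manifest = manifest, config = config)
    if (!is.null(outDir)) .writeRunArtifacts(result, outDir)
    result
}

.writeRunArtifacts <- function(result, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeHitsTabular(result$hits, file.path(outDir, "hits.tsv"))
    writeHitsTabular(result$candidates$comparisons,
                     file.path(outDir, "comparisons.tsv"))
    write.table(result$alignments, file.path(outDir, "alignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    acc <- result$accepted
    if (nrow(acc)) {
        keep <- contigs(result$libraryA)[unique(acc$query_id)]
        Biostrings::writeXStringSet(
            keep, file.path(outDir, "accepted_candidates.fasta"),
            width = 70L)
    }
    write.table(result$markers, file.path(outDir, "markers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$profiles, file.path(outDir, "profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$linkage, file.path(outDir, "linkage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(result$summary,
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(result$manifest,
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(result$manifest$report, file.path(outDir, "report.txt"))
    invisible(outDir)
}

#' Score a pipeline run against planted ground truth
#'
#' Computes per-stage confusion counts for a run on synthetic data. A
#' detectable alien pair is a pair of identical-by-descent contigs (one per
#' library, same gene and haplotype) whose fragment intervals share at
#' least `minExactLen` bp on the transcript. Sensitivity is the fraction of
#' detectable alien pairs accepted by the verification stage; precision is
#' the alien fraction among candidate comparisons and among accepted
#' pairs; `false_positive_carrier` counts markers with a carrier-level
#' linkage call whose source pair involves a recurrent-origin contig
#' (a homeologous donor copy paired with the alien haplotype is counted
#' separately in `n_carrier_calls_non_ibd`, since such a marker still
#' detects the alien chromosome).
#'
#' @param result the list returned by [runAll()].
#' @param truth a truth data.frame (defaults to `result$truth`).
#' @return A list of metrics; see Details.
#' @export
evaluateAgainstTruth <- function(result, truth = result$truth) {
    if (is.null(truth)) stop("no truth table available")
    allIds <- c(names(contigs(result$libraryA)),
                names(contigs(result$libraryB)))
    missing <- setdiff(allIds, truth$contig_id)
    if (length(missing))
        stop("truth table does not cover contig(s): ",
             paste(head(missing, 3), collapse = ", "))
    tr <- truth
    rownames(tr) <- tr$contig_id
    idsA <- names(contigs(result$libraryA))
    idsB <- names(contigs(result$libraryB))
    alienA <- tr[tr$contig_id %in% idsA & tr$origin == "alien_ibd", ,
                 drop = FALSE]
    alienB <- tr[tr$contig_id %in% idsB & tr$origin == "alien_ibd", ,
                 drop = FALSE]
    det <- merge(alienA, alienB,
                 by = c("gene_id", "copy_id"), suffixes = c("_a", "_b"))
    if (nrow(det)) {
        ov <- pmin(det$frag_end_a, det$frag_end_b) -
            pmax(det$frag_start_a, det$frag_start_b) + 1L
        det <- det[ov >= result$config@minExactLen, , drop = FALSE]
    }
    nDetect <- nrow(det)

    pairAlien <- function(q, s)
        tr[q, "origin"] == "alien_ibd" & tr[s, "origin"] == "alien_ibd" &
            tr[q, "gene_id"] == tr[s, "gene_id"]
    comp <- result$candidates$comparisons
    compPairs <- unique(comp[c("query_id", "subject_id")])
    acc <- result$accepted
    accAlien <- if (nrow(acc))
        sum(pairAlien(acc$query_id, acc$subject_id)) else 0L

    fpCarrier <- 0L
    carrierNonIbd <- 0L
    if (nrow(result$linkage)) {
        carrier <- result$linkage$call %in%
            c("carrier_linked", "asgr_tight")
        if (any(carrier)) {
            mk <- result$linkage[carrier, , drop = FALSE]
            partner <- result$markers$partner[
                match(mk$marker_id, result$markers$marker_id)]
            # a false positive involves a recurrent-origin contig; a
            # homeologous donor copy paired with the planted alien
            # haplotype still maps to the alien chromosome
            fpCarrier <- sum(tr[mk$candidate, "origin"] == "recurrent" |
                                 tr[partner, "origin"] == "recurrent")
            carrierNonIbd <- sum(!pairAlien(mk$candidate, partner))
        }
    }

    list(n_detectable_alien_pairs = nDetect,
         n_accepted_alien_pairs = accAlien,
         sensitivity = if (nDetect) accAlien / nDetect else NA_real_,
         precision_scan = if (nrow(compPairs))
             mean(pairAlien(compPairs$query_id, compPairs$subject_id))
         else NA_real_,
         precision_verify = if (nrow(acc))
             accAlien / nrow(acc) else NA_real_,
         n_accepted_pairs = nrow(acc),
         false_positive_carrier = fpCarrier,
         n_carrier_calls_non_ibd = carrierNonIbd,
         n_carrier_level_calls = if (nrow(result$linkage))
             sum(result$linkage$call %in%
                 c("carrier_linked", "asgr_tight")) else 0L)
}
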