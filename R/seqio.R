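## Readers/writers for the formats the pipeline touches: FASTA contig
## libraries and BLAST outfmt-6 compatible hit tables.

#' Read a contig library from FASTA
#'
#' Reads an assembled contig library. Sequences are upper-cased; the contig
#' id is the first whitespace-delimited token of the header. A read count is
#' parsed from the header when a `_x<N>` id suffix or a `numreads=<N>` token
#' is present (common assembler dialects); otherwise it is NA. An empty file
#' yields an empty library.
#'
#' @param path path to a FASTA file.
#' @param libraryId library identifier; defaults to the file base name.
#' @return A [ContigLibrary-class].
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 numreads=12", "ACGTACGT", ">c2", "ggttaa"), tf)
#' lib <- readContigs(tf, "demo")
#' readCounts(lib)
#' @export
readContigs <- function(path, libraryId = sub("\\.[^.]*$", "",
                                              basename(path))) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0)
        return(contigLibrary(libraryId, Biostrings::DNAStringSet()))
    first <- readLines(path, n = 50L, warn = FALSE)
    nonblank <- which(nzchar(trimws(first)))
    if (length(nonblank) && !startsWith(trimws(first[nonblank[1]]), ">"))
        stop("malformed FASTA in ", path, ": line ", nonblank[1],
             " does not start a record")
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    headers <- names(seqs)
    ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
    counts <- rep(NA_integer_, length(seqs))
    m <- regmatches(headers, regexpr("numreads=([0-9]+)", headers))
    has <- grepl("numreads=", headers)
    counts[has] <- as.integer(sub("numreads=", "", m))
    sufx <- grepl("_x[0-9]+$", ids)
    counts[sufx & is.na(counts)] <-
        as.integer(sub(".*_x([0-9]+)$", "\\1", ids[sufx & is.na(counts)]))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- ids
    contigLibrary(libraryId, seqs, counts)
}

#' Write a contig library to FASTA
#'
#' Sequences are wrapped at 70 columns, ids written as-is, so that two runs
#' on identical input produce byte-identical files.
#'
#' @param library a [ContigLibrary-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeContigs <- function(library, path) {
    Biostrings::writeXStringSet(contigs(library), path, width = 70L)
    invisible(path)
}

.hitColumns <- c("query_id", "subject_id", "identity", "length",
                 "mismatches", "gapopens", "qstart", "qend", "sstart",
                 "send", "evalue", "bitscore")

#' Write match hits as a BLAST outfmt-6 compatible table
#'
#' Twelve tab-separated columns: query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' E-value, bit score. Coordinates are 1-based inclusive; minus-strand hits
#' are encoded, as in BLAST, with sstart > send.
#'
#' @param hits a hit data.frame as returned by [findExactMatches()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeHitsTabular <- function(hits, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!nrow(hits)) return(invisible(path))
    sstart <- ifelse(hits$strand == "-", hits$send, hits$sstart)
    send <- ifelse(hits$strand == "-", hits$sstart, hits$send)
    out <- data.frame(hits$query_id, hits$subject_id,
                      sprintf("%.2f", 100 * hits$identity), hits$length,
                      hits$mismatches, hits$gapopens, hits$qstart,
                      hits$qend, sstart, send,
                      format(hits$evalue, digits = 3, scientific = TRUE),
                      sprintf("%.1f", hits$bitscore))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a BLAST outfmt-6 compatible hit table
#'
#' Inverse of [writeHitsTabular()]: reconstructs the internal hit layout
#' (forward-strand subject coordinates plus a strand column).
#'
#' @param path path to a 12-column tab-separated hit file.
#' @return A hit data.frame; zero rows for an empty file.
#' @export
readHitsTabular <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    empty <- data.frame(query_id = character(), subject_id = character(),
                        strand = character(), qstart = integer(),
                        qend = integer(), sstart = integer(),
                        send = integer(), length = integer(),
                        identity = numeric(), mismatches = integer(),
                        gapopens = integer(), score = numeric(),
                        bitscore = numeric(), evalue = numeric())
    if (file.size(path) == 0) return(empty)
    raw <- read.table(path, sep = "\t", header = FALSE,
                      col.names = .hitColumns,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "integer", "integer",
                                     "integer", "integer", "integer",
                                     "integer", "numeric", "numeric"))
    if (!nrow(raw)) return(empty)
    minus <- raw$sstart > raw$send
    data.frame(query_id = raw$query_id, subject_id = raw$subject_id,
               strand = ifelse(minus, "-", "+"), qstart = raw$qstart,
               qend = raw$qend,
               sstart = ifelse(minus, raw$send, raw$sstart),
               send = ifelse(minus, raw$sstart, raw$send),
               length = raw$length, identity = raw$identity / 100,
               mismatches = raw$mismatches, gapopens = raw$gapopens,
               score = NA_real_, bitscore = raw$bitscore,
               evalue = raw$evalue)
}
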