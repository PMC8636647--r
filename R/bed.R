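#' Read a BED3+ file as a sorted GRanges track
#'
#' Parses a tab-separated BED file (three or more columns; extra columns are
#' ignored) into a position-sorted \code{GRanges}. BED coordinates are
#' 0-based half-open; they are converted to the 1-based closed convention
#' \code{GRanges} uses, so a BED interval \code{[100, 200)} becomes
#' \code{101-200} and abutting BED intervals do not overlap. Header lines
#' starting with \code{track}, \code{browser} or \code{#} and blank lines
#' are skipped.
#'
#' @param path path to a BED file.
#' @param assembly optional \code{Seqinfo}; when supplied, a chromosome
#'   absent from the assembly or an interval past a chromosome end is an
#'   error. When absent, non-canonical chromosome names produce a warning
#'   but the rows are kept.
#' @param dedupe collapse identical \code{(chrom, start, end)} triplets
#'   (default \code{TRUE}).
#' @param trackName label stored as \code{metadata(gr)$name}.
#' @return a sorted \code{GRanges} (strand \code{*}; strand semantics are
#'   deliberately not used anywhere in this package).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t250", "chr2\t0\t50"), f)
#' readBed(f)
#' @export
readBed <- function(path, assembly = NULL, dedupe = TRUE,
                    trackName = basename(path)) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L) {
        gr <- GenomicRanges::GRanges()
        if (!is.null(assembly)) GenomeInfoDb::seqinfo(gr) <- assembly
        S4Vectors::metadata(gr)$name <- trackName
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", lineNo[which(nf < 3L)[1L]],
             ": fewer than 3 BED columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    startChr <- vapply(fields, `[[`, "", 2L)
    endChr <- vapply(fields, `[[`, "", 3L)
    start <- suppressWarnings(as.numeric(startChr))
    end <- suppressWarnings(as.numeric(endChr))
    bad <- !is.finite(start) | !is.finite(end) |
        start != floor(start) | end != floor(end) | start < 0
    if (any(bad))
        stop("line ", lineNo[which(bad)[1L]],
             ": malformed BED coordinates '", startChr[which(bad)[1L]], " ",
             endChr[which(bad)[1L]], "'")
    empty <- end <= start
    if (any(empty))
        stop("line ", lineNo[which(empty)[1L]], ": empty interval (end <= ",
             "start); BED intervals are half-open and must have end > start")
    gr <- makeTrack(chrom, start, end, assembly = assembly,
                    trackName = trackName)
    if (dedupe) gr <- unique(gr)
    gr
}

#' Build a sorted track from BED-convention coordinate vectors
#'
#' Constructs a position-sorted \code{GRanges} from 0-based half-open
#' coordinates (the convention of every tabular input this package reads),
#' enforcing assembly bounds when an assembly is given. This is the
#' conversion point between file-facing BED coordinates and the 1-based
#' closed coordinates \code{GRanges} uses internally.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param assembly optional \code{Seqinfo}.
#' @param trackName label stored in the track metadata.
#' @return a sorted \code{GRanges}.
#' @examples
#' makeTrack(c("chr2", "chr1"), c(0, 100), c(500, 200))
#' @export
makeTrack <- function(chrom, start, end, assembly = NULL,
                      trackName = NA_character_) {
    if (!is.null(assembly)) {
        known <- GenomeInfoDb::seqnames(assembly)
        if (!all(chrom %in% known))
            stop("chromosome(s) absent from assembly: ",
                 paste(unique(setdiff(chrom, known)), collapse = ", "))
        lens <- GenomeInfoDb::seqlengths(assembly)[chrom]
        if (any(end > lens))
            stop("interval end exceeds chromosome length on ",
                 chrom[which(end > lens)[1L]])
        levels <- known
    } else {
        if (!all(ok <- isCanonicalChrom(chrom)))
            warning("non-canonical chromosome name(s) kept: ",
                    paste(unique(chrom[!ok]), collapse = ", "))
        levels <- sort(unique(chrom))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = factor(chrom, levels = levels),
        ranges = IRanges::IRanges(start = start + 1, end = end))
    if (!is.null(assembly)) GenomeInfoDb::seqinfo(gr) <- assembly
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    S4Vectors::metadata(gr)$name <- trackName
    gr
}

#' Write a GRanges track as a BED3 file
#'
#' Inverse of \code{\link{readBed}}: internal 1-based closed coordinates are
#' written back as 0-based half-open BED, so a read/write/read round trip
#' reproduces the track exactly.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
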