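#' Load a promoter-capture Hi-C interaction table
#'
#' Reads a tab-separated table of promoter interactions (one row per
#' bait-promoter / PIR pair), drops interchromosomal rows, and collapses
#' the PIR fragments to a unique set. PIR identity is the exact coordinate
#' triple -- PIRs are restriction fragments, so no fuzzy merging is applied.
#' Each unique PIR retains the union of bait gene symbols over all its
#' interactions. All interval columns use the 0-based half-open (BED)
#' convention.
#'
#' @param path path to the TSV.
#' @param columns named character vector mapping the roles
#'   \code{baitChrom, baitStart, baitEnd, baitGenes, pirChrom, pirStart,
#'   pirEnd} to column names in the file.
#' @param geneSep regular expression separating multiple gene symbols within
#'   the bait-genes field (default splits on \code{;} or \code{,}).
#' @param assembly optional \code{Seqinfo} bounding the coordinates.
#' @return a list with elements \code{interactions} (data.frame of retained
#'   intrachromosomal rows), \code{pirs} (sorted \code{GRanges} of unique
#'   PIRs with a \code{genes} metadata list-column), and
#'   \code{nInterchromosomal} (count of dropped rows).
#' @export
loadPchic <- function(path,
                      columns = c(baitChrom = "bait_chrom",
                                  baitStart = "bait_start",
                                  baitEnd = "bait_end",
                                  baitGenes = "bait_genes",
                                  pirChrom = "pir_chrom",
                                  pirStart = "pir_start",
                                  pirEnd = "pir_end"),
                      geneSep = "[;,]", assembly = NULL) {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
    missing <- setdiff(unname(columns), colnames(tab))
    if (length(missing))
        stop("promoter-interaction table lacks required column(s): ",
             paste(missing, collapse = ", "))
    df <- data.frame(
        baitChrom = as.character(tab[[columns[["baitChrom"]]]]),
        baitStart = as.numeric(tab[[columns[["baitStart"]]]]),
        baitEnd   = as.numeric(tab[[columns[["baitEnd"]]]]),
        baitGenes = as.character(tab[[columns[["baitGenes"]]]]),
        pirChrom  = as.character(tab[[columns[["pirChrom"]]]]),
        pirStart  = as.numeric(tab[[columns[["pirStart"]]]]),
        pirEnd    = as.numeric(tab[[columns[["pirEnd"]]]]),
        stringsAsFactors = FALSE)
    intra <- df$baitChrom == df$pirChrom
    nInter <- sum(!intra)
    df <- df[intra, , drop = FALSE]
    if (nrow(df) == 0L)
        stop("no intrachromosomal interactions in ", path)

    key <- paste(df$pirChrom, df$pirStart, df$pirEnd, sep = ":")
    geneSplit <- strsplit(df$baitGenes, geneSep)
    geneSplit <- lapply(geneSplit, function(g) trimws(g[nzchar(trimws(g))]))
    genesByPir <- lapply(split(geneSplit, key),
                         function(gl) sort(unique(unlist(gl))))
    firstRow <- df[!duplicated(key), , drop = FALSE]
    ukey <- key[!duplicated(key)]
    pirs <- makeTrack(firstRow$pirChrom, firstRow$pirStart, firstRow$pirEnd,
                      assembly = assembly, trackName = "PIRs")
    # makeTrack sorts; recompute the key order to attach genes correctly
    sortedKey <- paste(as.character(GenomicRanges::seqnames(pirs)),
                       GenomicRanges::start(pirs) - 1L,
                       GenomicRanges::end(pirs), sep = ":")
    stopifnot(setequal(sortedKey, ukey))
    S4Vectors::mcols(pirs)$genes <- unname(genesByPir[sortedKey])
    list(interactions = df, pirs = pirs, nInterchromosomal = nInter)
}
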