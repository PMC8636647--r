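#' Load an RNA-DNA contact table (MARGI-style)
#'
#' Reads a tab-separated table of RNA-chromatin contacts, one row per
#' RNA-end / DNA-end coordinate pair (post-liftover). Rows whose RNA or DNA
#' end lies on an unlocalized or unplaced scaffold (name containing an
#' underscore, e.g. \code{chrUn_gl000220} or \code{chr7_gl000195_random}, or
#' a name outside the canonical/assembly chromosomes) are removed. Duplicate
#' pairs are collapsed so the result counts unique RNA-DNA interactions, and
#' the unique RNA-contacted DNA regions are returned as a separate track.
#' Interval columns use the 0-based half-open (BED) convention.
#'
#' @param path path to the TSV.
#' @param columns named character vector mapping roles
#'   \code{rnaChrom, rnaStart, rnaEnd, dnaChrom, dnaStart, dnaEnd} (and
#'   optionally \code{rnaName}) to file columns.
#' @param assembly optional \code{Seqinfo}.
#' @return a list with \code{contacts} (data.frame of unique retained
#'   pairs), \code{dnaRegions} (sorted \code{GRanges} of unique
#'   RNA-contacted DNA regions), \code{nRemovedScaffold} and
#'   \code{nDuplicates}.
#' @export
loadMargi <- function(path,
                      columns = c(rnaChrom = "rna_chrom",
                                  rnaStart = "rna_start",
                                  rnaEnd = "rna_end",
                                  dnaChrom = "dna_chrom",
                                  dnaStart = "dna_start",
                                  dnaEnd = "dna_end"),
                      assembly = NULL) {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
    missing <- setdiff(unname(columns), colnames(tab))
    if (length(missing))
        stop("RNA-DNA contact table lacks required column(s): ",
             paste(missing, collapse = ", "))
    df <- data.frame(
        rnaChrom = as.character(tab[[columns[["rnaChrom"]]]]),
        rnaStart = as.numeric(tab[[columns[["rnaStart"]]]]),
        rnaEnd   = as.numeric(tab[[columns[["rnaEnd"]]]]),
        dnaChrom = as.character(tab[[columns[["dnaChrom"]]]]),
        dnaStart = as.numeric(tab[[columns[["dnaStart"]]]]),
        dnaEnd   = as.numeric(tab[[columns[["dnaEnd"]]]]),
        stringsAsFactors = FALSE)
    if ("rnaName" %in% names(columns))
        df$rnaName <- as.character(tab[[columns[["rnaName"]]]])

    placed <- isCanonicalChrom(df$rnaChrom, assembly) &
        isCanonicalChrom(df$dnaChrom, assembly)
    nRemoved <- sum(!placed)
    df <- df[placed, , drop = FALSE]
    if (nrow(df) == 0L)
        stop("no placeable RNA-DNA contacts in ", path)

    pairKey <- paste(df$rnaChrom, df$rnaStart, df$rnaEnd,
                     df$dnaChrom, df$dnaStart, df$dnaEnd, sep = ":")
    dup <- duplicated(pairKey)
    nDup <- sum(dup)
    df <- df[!dup, , drop = FALSE]

    dnaKey <- paste(df$dnaChrom, df$dnaStart, df$dnaEnd, sep = ":")
    uniq <- !duplicated(dnaKey)
    dnaRegions <- makeTrack(df$dnaChrom[uniq], df$dnaStart[uniq],
                            df$dnaEnd[uniq], assembly = assembly,
                            trackName = "RNA-contacted DNA regions")
    list(contacts = df, dnaRegions = dnaRegions,
         nRemovedScaffold = nRemoved, nDuplicates = nDup)
}
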