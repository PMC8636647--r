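#' Read a chromosome-sizes table into a Seqinfo assembly
#'
#' Reads the standard two-column, tab-separated \code{chrom.sizes} format
#' (chromosome name, length in bp) and returns a
#' \code{\link[GenomeInfoDb]{Seqinfo}} describing the assembly. The
#' assembly bounds all interval containers in the package: intervals on
#' chromosomes absent from it, or extending past a chromosome end, are
#' rejected at construction time.
#'
#' @param path path to a chrom.sizes file.
#' @param genome optional assembly label (e.g. \code{"hg19"}).
#' @return a \code{Seqinfo} object.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t800"), f)
#' readChromSizes(f, genome = "toy")
#' @export
readChromSizes <- function(path, genome = NA_character_) {
    if (!file.exists(path))
        stop("chromosome-sizes file not found: ", path)
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "length"),
                      colClasses = c("character", "numeric"))
    makeAssembly(tab$chrom, tab$length, genome = genome)
}

#' Construct a Seqinfo assembly from name/length vectors
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths positive integer lengths in bp.
#' @param genome optional assembly label.
#' @return a \code{Seqinfo} object.
#' @export
makeAssembly <- function(chroms, lengths, genome = NA_character_) {
    if (anyDuplicated(chroms))
        stop("duplicated chromosome names in assembly")
    if (any(!is.finite(lengths)) || any(lengths <= 0) ||
        any(lengths != floor(lengths)))
        stop("chromosome lengths must be positive integers")
    GenomeInfoDb::Seqinfo(seqnames = as.character(chroms),
                          seqlengths = as.integer(lengths),
                          genome = genome)
}

#' Write a Seqinfo assembly as a chrom.sizes file
#'
#' @param assembly a \code{Seqinfo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChromSizes <- function(assembly, path) {
    write.table(
        data.frame(chrom = GenomeInfoDb::seqnames(assembly),
                   length = GenomeInfoDb::seqlengths(assembly)),
        path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Canonical chromosome detector. Any name containing an underscore
# (chrUn_gl000220, chr1_gl000191_random, ...) is unlocalized/unplaced and
# rejected. With an assembly bound, the name must additionally belong to it;
# without one, it must be a primary human-style chromosome.
isCanonicalChrom <- function(chrom, assembly = NULL) {
    if (!is.null(assembly)) {
        ok <- chrom %in% GenomeInfoDb::seqnames(assembly)
    } else {
        ok <- chrom %in% paste0("chr", c(1:22, "X", "Y", "M"))
    }
    ok & !grepl("_", chrom, fixed = TRUE)
}
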