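#' Flag query intervals overlapping any subject interval
#'
#' One logical per query interval: \code{TRUE} iff it shares at least one
#' base with some subject interval. Any degree of intersection counts; under
#' the half-open BED convention, abutting intervals share no base and do not
#' overlap. Both tracks must be position-sorted (as returned by
#' \code{\link{readBed}} and every track constructor in this package).
#'
#' @param query,subject sorted \code{GRanges} tracks.
#' @return logical vector of length \code{length(query)}.
#' @examples
#' q <- makeTrack("chr1", 100, 200)
#' s1 <- makeTrack("chr1", 199, 300)   # one shared base -> TRUE
#' s2 <- makeTrack("chr1", 200, 300)   # abutting -> FALSE
#' overlapFlags(q, s1); overlapFlags(q, s2)
#' @export
overlapFlags <- function(query, subject) {
    checkSorted(query, "query track")
    checkSorted(subject, "subject track")
    IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Consensus intervals supported by every track
#'
#' Computes the maximal genomic intervals covered simultaneously by all
#' input tracks: each track is first collapsed to its covered bases
#' (overlapping intervals merged), then the per-base intersection across
#' tracks is returned as a sorted, non-overlapping track. This implements
#' the all-replicates-agree rule used to derive high-confidence consensus
#' binding sites from multiple ENCODE peak tracks: a base belongs to the
#' consensus only if every dataset covers it.
#'
#' @param tracks a non-empty list of sorted \code{GRanges}.
#' @return a sorted, disjoint \code{GRanges}.
#' @examples
#' consensusIntervals(list(makeTrack("chr1", 0, 10), makeTrack("chr1", 5, 15)))
#' @export
consensusIntervals <- function(tracks) {
    if (!is.list(tracks) || length(tracks) == 0L)
        stop("'tracks' must be a non-empty list of GRanges")
    reduced <- lapply(tracks, function(gr) {
        checkSorted(gr)
        GenomicRanges::reduce(gr, ignore.strand = TRUE)
    })
    out <- Reduce(function(x, y)
        GenomicRanges::intersect(x, y, ignore.strand = TRUE), reduced)
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Randomly shuffle a track within the genome
#'
#' Re-places every interval uniformly at random in the assembly, preserving
#' its length: the chromosome is chosen with probability proportional to the
#' number of valid start positions it offers
#' (\code{chrom_length - interval_length + 1}) and the start is uniform over
#' those positions. Shuffled intervals may land on any chromosome and may
#' overlap one another; no regions are excluded. This is the null model used
#' to build randomised binding-site sets for the permutation test.
#'
#' @param track a \code{GRanges}.
#' @param assembly a \code{Seqinfo} bounding the placements.
#' @param seed integer seed; the same seed always reproduces the same
#'   placements, bit for bit.
#' @return a sorted \code{GRanges} with the same multiset of widths.
#' @export
shuffleTrack <- function(track, assembly, seed) {
    n <- length(track)
    lens <- GenomeInfoDb::seqlengths(assembly)
    if (any(is.na(lens))) stop("assembly must have defined chromosome lengths")
    if (n == 0L) {
        gr <- GenomicRanges::GRanges()
        GenomeInfoDb::seqinfo(gr) <- assembly
        return(gr)
    }
    w <- GenomicRanges::width(track)
    pl <- shufflePlacement(w, lens, seed)
    gr <- GenomicRanges::GRanges(
        seqnames = factor(names(lens)[pl$chromIdx], levels = names(lens)),
        ranges = IRanges::IRanges(start = pl$start0 + 1, width = w))
    GenomeInfoDb::seqinfo(gr) <- assembly
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# Numeric core of the shuffle: chromosome with probability proportional to
# its count of valid start positions, start uniform among them. Returns
# 0-based starts; shared by shuffleTrack and the permutation hot loop.
shufflePlacement <- function(w, lens, seed) {
    n <- length(w)
    if (any(w > max(lens)))
        stop("interval longer than every chromosome cannot be placed")
    k <- length(lens)
    # n x k matrix of valid start-position counts (0 where it cannot fit)
    avail <- outer(w, as.numeric(lens), function(wi, li) pmax(li - wi + 1, 0))
    for (j in seq_len(k)[-1]) avail[, j] <- avail[, j] + avail[, j - 1]
    withSeed(seed, {
        u <- runif(n) * avail[, k]
        chromIdx <- rowSums(u >= avail) + 1L
        maxStart <- as.numeric(lens)[chromIdx] - w + 1
        start0 <- floor(runif(n) * maxStart)   # 0-based start, < maxStart
    })
    list(chromIdx = chromIdx, start0 = start0)
}
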