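# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All randomised operations in the package route through this so
# results are reproducible given their `seed` argument alone.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    expr
}

#' Derive a reproducible sub-seed from a master seed and an index
#'
#' A documented, platform-stable integer mixing function used to give each
#' permutation (or generator substream) its own RNG seed:
#' \code{seed_i = (((seed mod m) * 69069 + i * 41651) mod m)} with
#' \code{m = 2^31 - 1}, computed in double precision (exact, since all
#' intermediates stay far below 2^53). Distinct indices map to distinct
#' sub-seeds for any fixed master seed because 69069 and m are coprime.
#'
#' @param seed master seed (integer).
#' @param i index (integer >= 0).
#' @return an integer sub-seed in [1, 2^31 - 2].
#' @export
subSeed <- function(seed, i) {
    m <- 2147483647
    s <- (as.numeric(seed) %% m)
    v <- (s * 69069 + as.numeric(i) * 41651) %% m
    as.integer(v + 1)
}

# Sorted-GRanges guard: overlap machinery assumes position-sorted tracks.
# O(n) lexicographic check on (chrom, start, end) integer vectors.
checkSorted <- function(gr, what = "track") {
    n <- length(gr)
    if (n <= 1L) return(invisible(TRUE))
    chr <- as.integer(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    i <- seq_len(n - 1L); j <- i + 1L
    ok <- chr[j] > chr[i] |
        (chr[j] == chr[i] & (s[j] > s[i] |
                                 (s[j] == s[i] & e[j] >= e[i])))
    if (!all(ok))
        stop(what, " is not sorted; sort it (e.g. sort(gr)) before use")
    invisible(TRUE)
}

# Write a data.frame as a plain TSV (the package's tabular output format).
writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# Machine-readable report writer; bare scalars, full precision.
writeReportJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

logMsg <- function(...) {
    message(format(Sys.time(), "%H:%M:%S "), ...)
}
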