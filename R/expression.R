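#' Read a transcript-level TPM table
#'
#' One file per replicate, tab-separated with columns
#' \code{transcript_id}, \code{gene_symbol}, \code{tpm}.
#'
#' @param path path to the TSV.
#' @return a data.frame with those three columns.
#' @export
readTpm <- function(path) {
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_symbol", "tpm")
    if (!all(need %in% colnames(tab)))
        stop("TPM table must have columns ", paste(need, collapse = ", "))
    tab[need]
}

#' Aggregate replicate transcript TPMs to gene-level TPM
#'
#' Replicate TPM values are averaged per transcript, then transcript TPMs
#' are summed within each gene (a gene's abundance is the total abundance
#' of its transcripts). A transcript mapping to more than one gene symbol
#' across replicates is an error; transcripts with an empty gene symbol are
#' excluded with a warning.
#'
#' @param replicates list of data.frames as returned by
#'   \code{\link{readTpm}} (>= 1 replicate).
#' @param transcriptAgg \code{"sum"} (default) or \code{"mean"}: how
#'   transcript TPMs combine into a gene value.
#' @return a data.frame with columns \code{gene} and \code{tpm}, one row
#'   per gene.
#' @examples
#' r1 <- data.frame(transcript_id = c("t1", "t2"),
#'                  gene_symbol = c("G1", "G1"), tpm = c(3, 7))
#' geneTpm(list(r1))          # G1: 10
#' @export
geneTpm <- function(replicates, transcriptAgg = c("sum", "mean")) {
    transcriptAgg <- match.arg(transcriptAgg)
    if (!is.list(replicates) || length(replicates) == 0L)
        stop("'replicates' must be a non-empty list of TPM tables")
    all <- do.call(rbind, replicates)
    if (anyNA(all$tpm) || any(all$tpm < 0))
        stop("TPM values must be non-negative and non-missing")
    blank <- !nzchar(trimws(all$gene_symbol))
    if (any(blank)) {
        warning(sum(blank), " transcript rows without a gene symbol ",
                "excluded")
        all <- all[!blank, , drop = FALSE]
    }
    map <- unique(all[c("transcript_id", "gene_symbol")])
    if (anyDuplicated(map$transcript_id))
        stop("transcript(s) mapped to more than one gene: ",
             paste(unique(map$transcript_id[duplicated(map$transcript_id)]),
                   collapse = ", "))
    # mean across replicates per transcript
    txTpm <- vapply(split(all$tpm, all$transcript_id), mean, numeric(1))
    gene <- map$gene_symbol[match(names(txTpm), map$transcript_id)]
    agg <- if (transcriptAgg == "sum") {
        rowsum(txTpm, gene)
    } else {
        rowsum(txTpm, gene) / as.vector(table(gene)[sort(unique(gene))])
    }
    data.frame(gene = rownames(agg), tpm = as.vector(agg),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-category expression summaries
#'
#' Attaches gene-level TPM values to each PIR-category gene list and
#' summarises them. Genes with no TPM entry are dropped (their count is
#' reported); a category left empty after the join is an error naming the
#' category. Genes shared between categories are retained in each.
#'
#' @param geneLists named list of character vectors (see
#'   \code{\link{geneListsByCategory}}).
#' @param expr gene-level table from \code{\link{geneTpm}}.
#' @return a list with \code{summary} (data.frame: category, nGenes,
#'   nMissing, meanTpm), and \code{tpms} (named list of per-category TPM
#'   vectors, gene-named).
#' @export
categoryExpression <- function(geneLists, expr) {
    stopifnot(is.list(geneLists), !is.null(names(geneLists)))
    tpms <- lapply(names(geneLists), function(nm) {
        g <- unique(geneLists[[nm]])
        idx <- match(g, expr$gene)
        found <- !is.na(idx)
        stats::setNames(expr$tpm[idx[found]], g[found])
    })
    names(tpms) <- names(geneLists)
    nMissing <- vapply(names(geneLists), function(nm)
        length(unique(geneLists[[nm]])) - length(tpms[[nm]]), integer(1))
    empty <- names(tpms)[lengths(tpms) == 0L]
    if (length(empty))
        stop("no expressed genes found for category: ",
             paste(empty, collapse = ", "))
    summary <- data.frame(
        category = names(tpms),
        nGenes = lengths(tpms),
        nMissing = nMissing,
        meanTpm = vapply(tpms, mean, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    list(summary = summary, tpms = tpms)
}

#' Mann-Whitney (Wilcoxon rank-sum) test with exact small-sample p
#'
#' Two-sided Mann-Whitney test comparing two samples. The U statistic is
#' computed from midranks (ties allowed). The p-value is exact (by
#' enumeration of rank assignments) when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors, all values finite.
#' @param method \code{"auto"} (the rule above), or force \code{"exact"}
#'   (small tie-free samples only) / \code{"approximate"}.
#' @return a list with \code{U} (the U statistic of \code{x}),
#'   \code{p} (two-sided), and \code{method}.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y, method = c("auto", "exact", "approximate")) {
    method <- match.arg(method)
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be non-empty")
    if (any(!is.finite(c(x, y))))
        stop("non-finite values in input")
    r <- rank(c(x, y))
    U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- switch(method,
                    auto = length(x) <= 8L && length(y) <= 8L && !ties,
                    exact = if (ties)
                        stop("exact p undefined with ties") else TRUE,
                    approximate = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "two.sided", exact = exact,
        correct = TRUE))
    list(U = unname(U), p = wt$p.value,
         method = if (exact) "exact" else "normal-approximation")
}
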