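#' Classify PIRs by overlap with RNA-contacted DNA regions
#'
#' Partitions unique promoter-interacting regions into RNA-associated PIRs
#' (RNA-PIRs) and non-RNA PIRs by positional overlap with the unique
#' RNA-contacted DNA regions: a PIR sharing at least one base with any
#' contacted region is an RNA-PIR.
#'
#' @param pirs sorted \code{GRanges} of unique PIRs (with a \code{genes}
#'   metadata list-column, as returned by \code{\link{loadPchic}}; a bare
#'   \code{GRanges} gets empty gene lists).
#' @param rnaRegions sorted \code{GRanges} of unique RNA-contacted DNA
#'   regions (see \code{\link{loadMargi}}).
#' @return a \code{\link{PirSet}} with \code{hasRna} populated.
#' @export
classifyPirs <- function(pirs, rnaRegions) {
    mc <- S4Vectors::mcols(pirs)
    if (!"genes" %in% colnames(mc))
        S4Vectors::mcols(pirs)$genes <-
            replicate(length(pirs), character(0), simplify = FALSE)
    S4Vectors::mcols(pirs)$hasRna <- overlapFlags(pirs, rnaRegions)
    methods::new("PirSet", ranges = pirs, factors = character(0))
}

#' Annotate PIRs with consensus binding-site overlap for a factor
#'
#' Sets the \code{has<Factor>} flag of each PIR according to overlap with
#' the factor's binding sites derived from one or more replicate tracks.
#' Two agreement rules are available for multi-track input:
#' \describe{
#'   \item{\code{"consensus"}}{(default) the PIR must overlap the per-base
#'     consensus of all tracks (\code{\link{consensusIntervals}}): every
#'     dataset supports the same bases.}
#'   \item{\code{"each-track"}}{the PIR must overlap every track somewhere,
#'     possibly at different positions.}
#' }
#' Any degree of intersection (>= 1 bp) counts in either rule.
#'
#' @param x a \code{\link{PirSet}}.
#' @param tracks a \code{GRanges} or list of \code{GRanges} (replicate
#'   binding-site datasets).
#' @param factor factor label, e.g. \code{"CTCF"} or \code{"YY1"}; must be
#'   a plain alphanumeric label starting with a letter.
#' @param rule agreement rule, see above.
#' @return \code{x} with the factor flag populated and the factor recorded
#'   in \code{tfbsFactors(x)}.
#' @export
annotateTfbs <- function(x, tracks, factor,
                         rule = c("consensus", "each-track")) {
    stopifnot(methods::is(x, "PirSet"))
    rule <- match.arg(rule)
    if (!is.character(factor) || length(factor) != 1L ||
        !grepl("^[A-Za-z][A-Za-z0-9]*$", factor))
        stop("unknown factor label: must be a single alphanumeric name, ",
             "got ", deparse(factor))
    if (methods::is(tracks, "GRanges")) tracks <- list(tracks)
    pirs <- x@ranges
    if (rule == "consensus") {
        cons <- consensusIntervals(tracks)
        flag <- overlapFlags(pirs, cons)
    } else {
        per <- vapply(tracks, function(tr) overlapFlags(pirs, tr),
                      logical(length(pirs)))
        per <- matrix(per, nrow = length(pirs))
        flag <- rowSums(per) == length(tracks)
    }
    S4Vectors::mcols(pirs)[[paste0("has", factor)]] <- flag
    methods::initialize(x, ranges = pirs,
                        factors = union(x@factors, factor))
}

#' Two-by-two counts of RNA status against binding-site status
#'
#' Cross-tabulates the PIRs by RNA association and binding-site presence
#' for one factor, returning the four cell counts and the percentage of
#' PIRs carrying the binding site within the RNA and non-RNA partitions.
#'
#' @param x an annotated \code{\link{PirSet}}.
#' @param factor an annotated factor label.
#' @return a list with integer cells \code{a} (RNA+/site+), \code{b}
#'   (RNA+/site-), \code{c} (RNA-/site+), \code{d} (RNA-/site-),
#'   percentages \code{pctRnaTfbs} (= 100 a/(a+b)) and \code{pctNonrnaTfbs}
#'   (= 100 c/(c+d)), the crude odds ratio \code{crudeOr} (= ad/bc) and
#'   \code{factor}.
#' @export
buildContingency <- function(x, factor) {
    stopifnot(methods::is(x, "PirSet"))
    rna <- hasRna(x)
    site <- hasTfbs(x, factor)
    if (anyNA(rna) || anyNA(site))
        stop("RNA or binding-site flags contain unset values; run ",
             "classifyPirs()/annotateTfbs() first")
    a <- sum(rna & site); b <- sum(rna & !site)
    c <- sum(!rna & site); d <- sum(!rna & !site)
    list(a = a, b = b, c = c, d = d,
         pctRnaTfbs = 100 * a / (a + b),
         pctNonrnaTfbs = 100 * c / (c + d),
         crudeOr = (a * d) / (b * c),
         factor = factor)
}

#' Unique gene lists for the four RNA-by-binding-site PIR categories
#'
#' For each cell of the RNA-status by binding-site-status cross (for one
#' factor) returns the union of bait gene symbols over the PIRs in that
#' cell, deduplicated within the cell. A gene contacting PIRs of several
#' categories appears in each corresponding list: the categories partition
#' PIRs, not genes. The lists are suitable for export to external ontology
#' tools (one symbol per line; see \code{\link{writeGeneLists}}).
#'
#' @param x an annotated \code{\link{PirSet}}.
#' @param factor an annotated factor label.
#' @return a named list of four sorted character vectors:
#'   \code{RNA_and_<factor>}, \code{RNA_only}, \code{<factor>_only},
#'   \code{neither}.
#' @export
geneListsByCategory <- function(x, factor) {
    stopifnot(methods::is(x, "PirSet"))
    rna <- hasRna(x)
    site <- hasTfbs(x, factor)
    if (anyNA(rna) || anyNA(site))
        stop("flags must be populated before extracting gene lists")
    genes <- pirGenes(x)
    cell <- function(sel) sort(unique(unlist(genes[sel])))
    out <- list(cell(rna & site), cell(rna & !site),
                cell(!rna & site), cell(!rna & !site))
    names(out) <- c(paste0("RNA_and_", factor), "RNA_only",
                    paste0(factor, "_only"), "neither")
    out
}

#' Write category gene lists as one-symbol-per-line text files
#'
#' @param lists result of \code{\link{geneListsByCategory}}.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
writeGeneLists <- function(lists, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(lists), function(nm) {
        p <- file.path(dir, paste0("genes_", nm, ".txt"))
        writeLines(lists[[nm]], p)
        p
    }, character(1))
    invisible(paths)
}

# ---- accessors & show ------------------------------------------------------

#' Accessors for PirSet objects
#'
#' \code{pirRanges} returns the underlying \code{GRanges};
#' \code{pirGenes} the per-PIR list of bait gene symbols; \code{hasRna} the
#' RNA-association flags; \code{hasTfbs} the binding-site flags for one
#' factor; \code{tfbsFactors} the factors annotated so far.
#'
#' @param x a \code{PirSet}.
#' @param factor a factor label previously passed to
#'   \code{\link{annotateTfbs}}.
#' @name PirSet-accessors
#' @aliases pirRanges pirGenes hasRna hasTfbs tfbsFactors
NULL

#' @rdname PirSet-accessors
#' @export
setMethod("pirRanges", "PirSet", function(x) x@ranges)

#' @rdname PirSet-accessors
#' @export
setMethod("pirGenes", "PirSet", function(x)
    as.list(S4Vectors::mcols(x@ranges)$genes))

#' @rdname PirSet-accessors
#' @export
setMethod("hasRna", "PirSet", function(x)
    S4Vectors::mcols(x@ranges)$hasRna)

#' @rdname PirSet-accessors
#' @export
setMethod("hasTfbs", "PirSet", function(x, factor) {
    col <- paste0("has", factor)
    mc <- S4Vectors::mcols(x@ranges)
    if (!col %in% colnames(mc))
        stop("factor '", factor, "' has not been annotated; available: ",
             if (length(x@factors)) paste(x@factors, collapse = ", ")
             else "<none>")
    mc[[col]]
})

#' @rdname PirSet-accessors
#' @export
setMethod("tfbsFactors", "PirSet", function(x) x@factors)

#' @describeIn PirSet number of unique PIRs.
#' @param x a \code{PirSet}.
#' @export
setMethod("length", "PirSet", function(x) length(x@ranges))

setMethod("show", "PirSet", function(object) {
    n <- length(object)
    rna <- hasRna(object)
    cat("PirSet with", n, "unique PIRs\n")
    if (!anyNA(rna))
        cat(sprintf("  RNA-PIRs: %d (%.1f%%)  nonRNA-PIRs: %d (%.1f%%)\n",
                    sum(rna), 100 * mean(rna),
                    sum(!rna), 100 * mean(!rna)))
    if (length(object@factors))
        for (f in object@factors) {
            fl <- hasTfbs(object, f)
            cat(sprintf("  %s consensus sites in %d PIRs (%.1f%%)\n",
                        f, sum(fl), 100 * mean(fl)))
        }
    invisible(NULL)
})
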