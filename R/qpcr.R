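#' Read a qPCR Ct table
#'
#' Comma-separated with columns \code{sample_id}, \code{group},
#' \code{target}, \code{replicate}, \code{ct}.
#'
#' @param path path to the CSV.
#' @return a data.frame with those columns.
#' @export
readCt <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "target", "replicate", "ct")
    if (!all(need %in% colnames(tab)))
        stop("Ct table must have columns ", paste(need, collapse = ", "))
    if (any(!is.finite(tab$ct)))
        stop("non-finite Ct values")
    tab[need]
}

# Per-unit delta-Ct values (Ct_target - Ct_reference) for one group.
# Target and reference wells are matched by (sample_id, replicate). When a
# group contains two or more samples, technical replicates are averaged
# within sample and the samples are the statistical units; with a single
# sample the replicates themselves are the units.
groupDeltaCt <- function(measurements, target, reference, group) {
    m <- measurements[measurements$group == group, , drop = FALSE]
    tg <- m[m$target == target, , drop = FALSE]
    rf <- m[m$target == reference, , drop = FALSE]
    if (nrow(tg) == 0L)
        stop("no measurements of target '", target, "' in group '",
             group, "'")
    if (nrow(rf) == 0L)
        stop("missing reference assay '", reference, "' in group '",
             group, "'")
    key <- function(d) paste(d$sample_id, d$replicate, sep = "\r")
    idx <- match(key(tg), key(rf))
    if (anyNA(idx))
        stop("unmatched target/reference replicates in group '", group, "'")
    delta <- tg$ct - rf$ct[idx]
    sample <- tg$sample_id
    if (length(unique(sample)) >= 2L)
        delta <- vapply(split(delta, sample), mean, numeric(1))
    if (length(delta) < 2L)
        stop("group '", group, "' needs at least two delta-Ct values ",
             "for a standard error")
    delta
}

#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' Computes, per statistical unit, \code{dCt = Ct_target - Ct_reference};
#' then \code{ddCt = mean dCt(test) - mean dCt(control)} and the fold
#' change \code{2^-ddCt}. Means and standard errors are calculated on the
#' dCt scale (where replicate noise is approximately normal); the standard
#' error of ddCt pools the two group SEs,
#' \code{sqrt(SE_test^2 + SE_control^2)}, and the fold interval
#' \code{2^-(ddCt +- SE)} is reported asymmetrically, without delta-method
#' symmetrisation. A Welch t-test on the dCt values gives the p-value,
#' Bonferroni-adjusted by the comparison count \code{m}.
#'
#' Because dCt subtracts the reference assay within each unit, a constant
#' plate offset added to every Ct cancels exactly; and swapping the test
#' and control groups maps the fold to its reciprocal.
#'
#' @param measurements data.frame as from \code{\link{readCt}}.
#' @param target assay to quantify.
#' @param reference internal-control assay measured in the same units
#'   (the expression analyses use an IPO8 assay; 3C uses an ERCC3
#'   interaction junction, see \code{\link{quantify3c}}).
#' @param controlGroup,testGroup group labels; fold is test relative to
#'   control (control fold is 1 by construction).
#' @param m number of comparisons for the Bonferroni adjustment
#'   (default 1).
#' @return a list with \code{target}, \code{reference}, \code{groups},
#'   \code{deltaCtMean} (named, both groups), \code{ddct}, \code{fold},
#'   \code{seDdct}, \code{foldInterval} (low/high), \code{pRaw},
#'   \code{pAdj}, \code{nUnits}.
#' @examples
#' ct <- data.frame(
#'   sample_id = rep(c("c1", "c2", "t1", "t2"), each = 2),
#'   group = rep(c("control", "control", "treated", "treated"), each = 2),
#'   target = rep(c("GENE", "REF"), 4),
#'   replicate = 1,
#'   ct = c(25, 20, 25.2, 20.2, 24.1, 20.1, 23.9, 19.9))
#' deltaDeltaCt(ct, "GENE", "REF", "control", "treated")$fold  # 2
#' @export
deltaDeltaCt <- function(measurements, target, reference, controlGroup,
                         testGroup, m = 1L) {
    groups <- unique(measurements$group)
    if (!controlGroup %in% groups || !testGroup %in% groups)
        stop("group(s) not present in the data: ",
             paste(setdiff(c(controlGroup, testGroup), groups),
                   collapse = ", "))
    dCtrl <- groupDeltaCt(measurements, target, reference, controlGroup)
    dTest <- groupDeltaCt(measurements, target, reference, testGroup)
    ddct <- mean(dTest) - mean(dCtrl)
    seCtrl <- stats::sd(dCtrl) / sqrt(length(dCtrl))
    seTest <- stats::sd(dTest) / sqrt(length(dTest))
    seDdct <- sqrt(seCtrl^2 + seTest^2)
    tt <- welchP(dTest, dCtrl)
    list(target = target, reference = reference,
         groups = c(control = controlGroup, test = testGroup),
         deltaCtMean = c(control = mean(dCtrl), test = mean(dTest)),
         ddct = ddct, fold = 2^(-ddct), seDdct = seDdct,
         foldInterval = c(low = 2^(-(ddct + seDdct)),
                          high = 2^(-(ddct - seDdct))),
         pRaw = tt, pAdj = min(1, m * tt),
         nUnits = c(control = length(dCtrl), test = length(dTest)))
}

# Two-sided Welch t-test p-value; degenerate zero-variance/equal-mean
# inputs give p = 1 with a warning rather than NaN.
welchP <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) {
            warning("zero variance in both groups with equal means; p = 1")
            return(1)
        }
        return(.Machine$double.xmin)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Welch t-tests with Bonferroni correction across comparisons
#'
#' Compares each non-control group's delta-Ct values against the control
#' group with a two-sided Welch (unequal-variance) t-test; p-values are
#' adjusted as \code{min(1, m * p)}.
#'
#' @param deltaCtGroups named list of numeric delta-Ct vectors; the first
#'   element is the control group.
#' @param m number of comparisons (default: number of non-control groups).
#' @return a data.frame with columns \code{group}, \code{pRaw},
#'   \code{pAdj}.
#' @export
ttestBonferroni <- function(deltaCtGroups,
                            m = length(deltaCtGroups) - 1L) {
    stopifnot(is.list(deltaCtGroups), length(deltaCtGroups) >= 2L,
              !is.null(names(deltaCtGroups)))
    if (any(lengths(deltaCtGroups) < 2L))
        stop("every group needs >= 2 delta-Ct values")
    control <- deltaCtGroups[[1L]]
    others <- names(deltaCtGroups)[-1L]
    pRaw <- vapply(others, function(g)
        welchP(deltaCtGroups[[g]], control), numeric(1))
    data.frame(group = others, pRaw = pRaw,
               pAdj = pmin(1, m * pRaw),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify a chromatin-interaction junction from 3C-qPCR
#'
#' Relative interaction frequency of a ligation junction versus the control
#' group, using an invariant positive-control interaction (by default an
#' ERCC3 junction) as the internal reference: a thin wrapper around
#' \code{\link{deltaDeltaCt}}. A ddCt of -1 between test and control means
#' the interaction frequency doubled.
#'
#' @param measurements data.frame as from \code{\link{readCt}}.
#' @param junction junction assay label to quantify.
#' @param reference internal-control junction (default \code{"ERCC3"}).
#' @param controlGroup,testGroup,m as in \code{\link{deltaDeltaCt}}.
#' @return see \code{\link{deltaDeltaCt}}.
#' @export
quantify3c <- function(measurements, junction, reference = "ERCC3",
                       controlGroup, testGroup, m = 1L) {
    deltaDeltaCt(measurements, target = junction, reference = reference,
                 controlGroup = controlGroup, testGroup = testGroup, m = m)
}
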