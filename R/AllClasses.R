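#' PirSet: a set of unique promoter-interacting regions with annotations
#'
#' Container for the unique promoter-interacting regions (PIRs) of a
#' promoter-capture Hi-C experiment. Each PIR is a restriction fragment
#' (a \code{GRanges} element) carrying the union of bait gene symbols over
#' all promoter interactions it participates in, plus logical flags set by
#' \code{\link{classifyPirs}} (overlap with RNA-contacted DNA regions) and
#' \code{\link{annotateTfbs}} (overlap with consensus binding sites, one
#' flag per factor). Flags are \code{NA} until the corresponding annotation
#' step has run.
#'
#' @slot ranges \code{GRanges} of unique PIR fragments; metadata columns
#'   \code{genes} (list of character vectors), \code{hasRna} (logical) and
#'   one logical column \code{has<Factor>} per annotated factor.
#' @slot factors character vector of factor labels annotated so far.
#'
#' @seealso \code{\link{classifyPirs}}, \code{\link{annotateTfbs}},
#'   \code{\link{buildContingency}}, \code{\link{geneListsByCategory}}
#' @exportClass PirSet
setClass("PirSet",
    slots = c(ranges = "GRanges", factors = "character"))

setValidity("PirSet", function(object) {
    mc <- S4Vectors::mcols(object@ranges)
    msg <- character()
    if (!all(c("genes", "hasRna") %in% colnames(mc)))
        msg <- c(msg, "metadata columns 'genes' and 'hasRna' are required")
    if ("genes" %in% colnames(mc) && !is.list(mc$genes) &&
        !methods::is(mc$genes, "List"))
        msg <- c(msg, "'genes' must be a list of character vectors")
    if ("hasRna" %in% colnames(mc) && !is.logical(mc$hasRna))
        msg <- c(msg, "'hasRna' must be logical")
    for (f in object@factors) {
        col <- paste0("has", f)
        if (!col %in% colnames(mc) || !is.logical(mc[[col]]))
            msg <- c(msg, sprintf("missing or non-logical column '%s'", col))
    }
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: logistic-regression enrichment summary
#'
#' Wald summary of a binary logistic regression testing whether a feature
#' (e.g. a consensus CTCF binding site) is enriched in RNA-associated PIRs,
#' with fragment size optionally included as a covariate.
#'
#' @slot beta log-odds estimate for the exposure term.
#' @slot se standard error of \code{beta}.
#' @slot orValue odds ratio, \code{exp(beta)}.
#' @slot ciLow,ciHigh Wald confidence bounds for the odds ratio.
#' @slot level confidence level (default 0.95).
#' @slot pWald two-sided Wald p-value.
#' @slot nObs number of observations in the fit.
#' @slot covariateSpec one of \code{"log10-length"}, \code{"raw-length"},
#'   \code{"none"}.
#' @slot direction regression direction, \code{"tfbs-on-rna"} (feature
#'   presence modelled on RNA status) or \code{"rna-on-tfbs"}.
#'
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    slots = c(beta = "numeric", se = "numeric", orValue = "numeric",
              ciLow = "numeric", ciHigh = "numeric", level = "numeric",
              pWald = "numeric", nObs = "integer",
              covariateSpec = "character", direction = "character"))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (object@orValue <= 0) msg <- c(msg, "odds ratio must be positive")
    if (!(object@ciLow <= object@orValue && object@orValue <= object@ciHigh))
        msg <- c(msg, "CI must bracket the odds ratio")
    if (!(object@pWald > 0 && object@pWald <= 1))
        msg <- c(msg, "pWald must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' PermutationResult: shuffled-interval permutation null summary
#'
#' Result of comparing an observed logistic-regression p-value against the
#' p-values obtained when the consensus feature track is randomly shuffled
#' within the genome and the identical regression re-fitted.
#'
#' @slot nPerm number of permutations that yielded a valid fit.
#' @slot nRequested number of permutations requested.
#' @slot rLower count of permuted p-values strictly below the observed one.
#' @slot pPerm add-one permutation p-value, \code{(rLower + 1)/(nPerm + 1)}.
#' @slot observedP observed Wald p-value.
#' @slot permP numeric vector of permuted Wald p-values.
#' @slot seed integer seed that drove the shuffles.
#'
#' @exportClass PermutationResult
setClass("PermutationResult",
    slots = c(nPerm = "integer", nRequested = "integer", rLower = "integer",
              pPerm = "numeric", observedP = "numeric", permP = "numeric",
              seed = "integer"))

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (object@rLower < 0L || object@rLower > object@nPerm)
        msg <- c(msg, "rLower must lie in [0, nPerm]")
    if (!(object@pPerm > 0 && object@pPerm <= 1))
        msg <- c(msg, "pPerm must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})
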