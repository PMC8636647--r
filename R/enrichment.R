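#' Binary logistic regression for binding-site enrichment
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares)
#' of a binary outcome on a binary exposure, with an optional numeric
#' covariate. In the enrichment analysis the outcome is binding-site
#' presence, the exposure RNA-PIR status, and the covariate (log) fragment
#' length, which confounds both flags because longer fragments are more
#' likely to overlap anything.
#'
#' Without a covariate the model is saturated and \code{exp(beta)} of the
#' exposure equals the sample 2x2 odds ratio exactly.
#'
#' @param outcome,exposure logical vectors of equal length, no missing
#'   values.
#' @param covariate optional numeric vector (same length).
#' @return a list with \code{coef} (named: intercept, exposure and, when
#'   present, covariate), \code{vcov} (inverse observed information),
#'   \code{n}, and \code{converged}.
#' @examples
#' ## 2x2 counts a=10, b=20, c=30, d=40: exposure coefficient is ln(2/3)
#' y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 20, 30, 40))
#' e <- rep(c(TRUE, FALSE), c(30, 70))
#' fitLogistic(y, e)$coef[["exposure"]]
#' @export
fitLogistic <- function(outcome, exposure, covariate = NULL) {
    outcome <- as.logical(outcome); exposure <- as.logical(exposure)
    n <- length(outcome)
    if (length(exposure) != n)
        stop("outcome and exposure lengths differ")
    if (anyNA(outcome) || anyNA(exposure))
        stop("missing values are not allowed")
    X <- cbind(intercept = 1, exposure = as.numeric(exposure))
    if (!is.null(covariate)) {
        if (length(covariate) != n || anyNA(covariate) ||
            any(!is.finite(covariate)))
            stop("covariate must be finite and match the record count")
        X <- cbind(X, covariate = as.numeric(covariate))
    }
    fitLogisticRaw(X, outcome)
}

# IRLS core shared by the user-facing fit and the permutation loop.
# glm.fit performs the IRLS; separation is flagged when any coefficient
# diverges beyond +-30 on the log-odds scale (odds ratios beyond e^30 have
# no finite MLE in practice).
fitLogisticRaw <- function(X, y) {
    y <- as.numeric(y)
    if (all(y == 1) || all(y == 0))
        stop("outcome has a single class; logistic fit undefined")
    fit <- suppressWarnings(stats::glm.fit(
        x = X, y = y, family = stats::binomial(),
        control = list(epsilon = 1e-14, maxit = 100)))
    beta <- fit$coefficients
    if (anyNA(beta))
        stop("rank-deficient design; drop collinear terms")
    if (any(abs(beta) > 30))
        stop("complete or quasi-complete separation detected ",
             "(coefficient beyond +-30 log-odds)")
    p <- fit$rank
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    vcov <- chol2inv(R)
    dimnames(vcov) <- list(colnames(X), colnames(X))
    list(coef = stats::setNames(beta, colnames(X)), vcov = vcov,
         n = length(y), converged = fit$converged)
}

#' Wald summary of a logistic enrichment fit
#'
#' Exponentiates the exposure coefficient into an odds ratio with Wald
#' confidence bounds \code{exp(beta +- z se)} and a two-sided normal
#' p-value.
#'
#' @param fit result of \code{\link{fitLogistic}}.
#' @param level confidence level (default 0.95, i.e. z = 1.959964).
#' @param term coefficient to summarise (default \code{"exposure"}).
#' @param covariateSpec,direction labels recorded in the result.
#' @return an \code{\link{EnrichmentResult}}.
#' @export
waldSummary <- function(fit, level = 0.95, term = "exposure",
                        covariateSpec = if ("covariate" %in% names(fit$coef))
                            "log10-length" else "none",
                        direction = "tfbs-on-rna") {
    beta <- fit$coef[[term]]
    se <- sqrt(fit$vcov[term, term])
    if (!is.finite(se)) stop("non-finite standard error")
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- 2 * stats::pnorm(-abs(beta / se))
    p <- max(p, .Machine$double.xmin)   # keep p in (0, 1]
    methods::new("EnrichmentResult",
                 beta = beta, se = se, orValue = exp(beta),
                 ciLow = exp(beta - z * se), ciHigh = exp(beta + z * se),
                 level = level, pWald = p, nObs = as.integer(fit$n),
                 covariateSpec = covariateSpec, direction = direction)
}

#' Enrichment of a binding-site factor in RNA-PIRs
#'
#' Convenience wrapper running the binary logistic regression on an
#' annotated \code{\link{PirSet}}. By default binding-site presence is
#' modelled on RNA-PIR status with log10 fragment length as covariate;
#' both the regression direction and the covariate scale are configurable
#' because fragment lengths span orders of magnitude and the two directions
#' give slightly different odds ratios once the covariate enters.
#'
#' @param x an annotated \code{\link{PirSet}}.
#' @param factor an annotated factor label.
#' @param covariate \code{"log10-length"} (default), \code{"raw-length"}
#'   or \code{"none"}.
#' @param direction \code{"tfbs-on-rna"} (default: outcome = site presence,
#'   exposure = RNA status) or \code{"rna-on-tfbs"}.
#' @param level confidence level for the Wald interval.
#' @return an \code{\link{EnrichmentResult}}.
#' @export
enrichmentTest <- function(x, factor,
                           covariate = c("log10-length", "raw-length",
                                         "none"),
                           direction = c("tfbs-on-rna", "rna-on-tfbs"),
                           level = 0.95) {
    covariate <- match.arg(covariate)
    direction <- match.arg(direction)
    rna <- hasRna(x)
    site <- hasTfbs(x, factor)
    len <- GenomicRanges::width(pirRanges(x))
    cov <- switch(covariate,
                  "log10-length" = log10(len),
                  "raw-length" = as.numeric(len),
                  "none" = NULL)
    if (direction == "tfbs-on-rna")
        fit <- fitLogistic(site, rna, cov)
    else
        fit <- fitLogistic(rna, site, cov)
    waldSummary(fit, level = level, covariateSpec = covariate,
                direction = direction)
}

# ---- accessors & show ------------------------------------------------------

#' Accessors for EnrichmentResult objects
#'
#' @param x an \code{EnrichmentResult}.
#' @name EnrichmentResult-accessors
#' @aliases oddsRatio confInt pValue
NULL

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("oddsRatio", "EnrichmentResult", function(x) x@orValue)

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("confInt", "EnrichmentResult",
          function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@pWald)

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult (%s, covariate: %s, n = %d)\n",
        object@direction, object@covariateSpec, object@nObs))
    cat(sprintf("  OR = %.3f; %d%% CI = %.3f-%.3f; P = %.3g\n",
                object@orValue, round(100 * object@level),
                object@ciLow, object@ciHigh, object@pWald))
    invisible(NULL)
})
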