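# Independent oracles and small fixture builders shared across the suite.
# Every oracle here is deliberately naive (all-pairs loops, per-base masks,
# direct likelihood maximisation, exhaustive rank enumeration) so it shares
# no code path with the implementation it checks.

toyAssembly <- function(lens = c(chr1 = 10000, chr2 = 8000)) {
    makeAssembly(names(lens), unname(lens))
}

# Random BED-convention track as a plain data.frame plus its GRanges form.
randomBedTrack <- function(n, assembly, maxLen = 300) {
    chroms <- GenomeInfoDb::seqnames(assembly)
    lens <- GenomeInfoDb::seqlengths(assembly)
    chrom <- sample(chroms, n, replace = TRUE)
    w <- sample.int(maxLen, n, replace = TRUE)
    start <- floor(runif(n) * (lens[chrom] - w))
    df <- data.frame(chrom = chrom, start = start, end = start + w,
                     stringsAsFactors = FALSE)
    list(df = df, gr = makeTrack(df$chrom, df$start, df$end,
                                 assembly = assembly))
}

# All-pairs overlap oracle on BED (half-open) coordinates.
bruteOverlapFlags <- function(qdf, sdf) {
    vapply(seq_len(nrow(qdf)), function(i) {
        any(qdf$chrom[i] == sdf$chrom &
                qdf$start[i] < sdf$end & sdf$start < qdf$end[i])
    }, logical(1))
}

# Per-base consensus oracle: positions (0-based) covered by every track,
# grouped into runs, returned as a BED data.frame.
perBaseConsensus <- function(dfs, assembly) {
    lens <- GenomeInfoDb::seqlengths(assembly)
    out <- NULL
    for (ch in names(lens)) {
        mask <- rep(TRUE, lens[[ch]])
        for (df in dfs) {
            m <- rep(FALSE, lens[[ch]])
            rows <- df[df$chrom == ch, , drop = FALSE]
            for (i in seq_len(nrow(rows)))
                m[(rows$start[i] + 1):rows$end[i]] <- TRUE
            mask <- mask & m
        }
        if (!any(mask)) next
        r <- rle(mask)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths    # 0-based run starts
        keep <- r$values
        if (any(keep))
            out <- rbind(out, data.frame(chrom = ch,
                                         start = starts[keep],
                                         end = ends[keep]))
    }
    out
}

grToBed <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

# Direct maximisation of the logistic log-likelihood (BFGS with analytic
# gradient), independent of the IRLS route.
logitOracle <- function(X, y) {
    nll <- function(b) {
        eta <- as.vector(X %*% b)
        sum(log1p(exp(eta))) - sum(y * eta)
    }
    grad <- function(b) {
        eta <- as.vector(X %*% b)
        as.vector(t(X) %*% (plogis(eta) - y))
    }
    stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))$par
}

# Exhaustive Mann-Whitney two-sided p by enumerating all rank assignments.
exactMwP <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vals <- c(x, y)
    stopifnot(!anyDuplicated(vals))
    idx <- utils::combn(nx + ny, nx)
    r <- rank(vals)
    uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    uAll <- apply(idx, 2, function(ii)
        sum(rank(vals)[ii]) - nx * (nx + 1) / 2)
    min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs)))
}

# Small, fast synthetic config for module tests.
smallConfig <- function(seed, ...) {
    syntheticConfig(seed = seed, nChroms = 3L, chromLength = 8e6,
                    nPirs = 800L, nGenes = 600L, ...)
}
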