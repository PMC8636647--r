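#' Configuration for the synthetic interactome generator
#'
#' Bundles every parameter of the synthetic data model with defaults
#' emulating the statistical structure of a promoter-capture Hi-C /
#' RNA-chromatin integration study in hESCs:
#' \itemize{
#'   \item PIR fragments with a log-normal, HindIII-like length
#'     distribution (median ~4 kb), tiled without overlap along the
#'     synthetic chromosomes;
#'   \item RNA-contact attachment following a logistic model in log10
#'     fragment length (longer fragments are more often contacted --
#'     deliberate confounding);
#'   \item binding-site presence following a logistic model with a planted
#'     conditional odds ratio \code{exp(tfbsLogOr)} for RNA status and its
#'     own length term, so the covariate-adjusted regression is correctly
#'     specified and the crude 2x2 odds ratio is biased away;
#'   \item replicate binding-site tracks that are jittered copies of the
#'     true placements, mirroring ENCODE replicate concordance, so the
#'     all-tracks-agree consensus recovers the planted flags exactly;
#'   \item log-normal TPM with multiplicative category effects;
#'   \item Ct tables with planted group fold changes and replicate noise.
#' }
#'
#' @param seed master seed; all randomness flows from it through named
#'   substreams (placement, RNA, binding sites, genes, expression, qPCR).
#' @param nChroms,chromLength synthetic assembly: chromosomes
#'   \code{chr1..chrN}, equal length in bp.
#' @param nPirs number of unique PIR fragments.
#' @param pirLengthMeanlog,pirLengthSdlog log-normal fragment-length
#'   parameters (natural-log scale, bp).
#' @param pirLengthRange clamp for fragment lengths, bp.
#' @param rnaIntercept,rnaLengthSlope logistic model
#'   \code{logit P(hasRna) = rnaIntercept + rnaLengthSlope * log10(len)}.
#' @param tfbsIntercept,tfbsLogOr,tfbsLengthSlope logistic model
#'   \code{logit P(site) = tfbsIntercept + tfbsLogOr * hasRna +
#'   tfbsLengthSlope * log10(len)}; \code{exp(tfbsLogOr)} is the planted
#'   conditional odds ratio.
#' @param tfbsFactor factor label for the binding-site tracks.
#' @param tfbsWidth width of a planted binding site, bp.
#' @param nTracks number of replicate binding-site tracks.
#' @param jitter maximal per-endpoint displacement of a replicate track
#'   copy, bp; must satisfy \code{2 * jitter < tfbsWidth} or the consensus
#'   would vanish.
#' @param backgroundRate background binding sites (placed between PIRs)
#'   per planted site.
#' @param genesPerPirLambda genes per PIR drawn as
#'   \code{1 + Poisson(lambda)}.
#' @param nGenes size of the gene universe.
#' @param exprMeanlog,exprSdlog baseline log-normal TPM.
#' @param exprEffects multiplicative TPM effect per PIR category (names
#'   \code{RNA_and_TFBS}, \code{RNA_only}, \code{TFBS_only},
#'   \code{neither}).
#' @param exprNoiseSdlog replicate noise on the log-TPM scale.
#' @param transcriptsPerGene transcripts per gene (TPM split randomly).
#' @param qpcrNoiseSd replicate noise of Ct values, cycles.
#' @param qpcrFolds planted expression fold changes (test group vs
#'   control) for the assayed genes.
#' @param qpcr3cFold planted interaction-frequency fold change of the
#'   promoter-PIR junction.
#' @param nQpcrSamples biological samples per group.
#' @return a validated list of class \code{rnapirConfig}.
#' @export
syntheticConfig <- function(seed,
                            nChroms = 5L,
                            chromLength = 5e7,
                            nPirs = 20000L,
                            pirLengthMeanlog = log(4000),
                            pirLengthSdlog = 0.8,
                            pirLengthRange = c(500, 50000),
                            rnaIntercept = -4.0,
                            rnaLengthSlope = 1.0,
                            tfbsIntercept = -5.8,
                            tfbsLogOr = log(1.78),
                            tfbsLengthSlope = 1.0,
                            tfbsFactor = "CTCF",
                            tfbsWidth = 200L,
                            nTracks = 3L,
                            jitter = 10L,
                            backgroundRate = 0.5,
                            genesPerPirLambda = 0.3,
                            nGenes = 12000L,
                            exprMeanlog = log(5),
                            exprSdlog = 1.2,
                            exprEffects = c(RNA_and_TFBS = 3,
                                            RNA_only = 1.5,
                                            TFBS_only = 1,
                                            neither = 1),
                            exprNoiseSdlog = 0.1,
                            transcriptsPerGene = 2L,
                            qpcrNoiseSd = 0.1,
                            qpcrFolds = c(MSX1 = 2, STX18AS1 = 0.25),
                            qpcr3cFold = 2,
                            nQpcrSamples = 3L) {
    if (missing(seed)) stop("config requires a seed")
    cfg <- as.list(environment())
    if (2 * cfg$jitter >= cfg$tfbsWidth)
        stop("jitter must be less than half the binding-site width, or ",
             "the replicate-track consensus would vanish")
    if (cfg$pirLengthRange[1] < cfg$tfbsWidth + 2 * (cfg$jitter + 1))
        stop("minimum PIR length too small to host a binding site with ",
             "jitter margins")
    if (!all(c("RNA_and_TFBS", "RNA_only", "TFBS_only", "neither") %in%
             names(cfg$exprEffects)))
        stop("exprEffects must name all four PIR categories")
    structure(cfg, class = "rnapirConfig")
}

#' Simulate a synthetic interactome in memory
#'
#' Core of the generator: draws PIR fragments, RNA flags, binding-site
#' flags and placements, replicate tracks, genes, expression and qPCR data
#' according to a \code{\link{syntheticConfig}}, fully deterministically
#' given the config seed. \code{\link{generateDataset}} serialises the
#' result into the file formats the pipeline consumes.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a list with \code{assembly} (Seqinfo), \code{pirs} (GRanges with
#'   \code{genes}), \code{hasRna}/\code{hasTfbs} (planted flags),
#'   \code{tfbsTrue} (GRanges of true sites incl. background),
#'   \code{tracks} (list of jittered replicate GRanges),
#'   \code{rnaRegions} (GRanges of contacted DNA regions),
#'   \code{contacts}/\code{pchic} (data.frames in file layout, BED
#'   coordinates), \code{tpm} (list of replicate transcript tables),
#'   \code{ct} (Ct table), and \code{truth} (planted ground truth).
#' @export
simulatePirData <- function(config) {
    stopifnot(inherits(config, "rnapirConfig"))
    cfg <- config
    assembly <- makeAssembly(paste0("chr", seq_len(cfg$nChroms)),
                             rep(cfg$chromLength, cfg$nChroms),
                             genome = "synthetic")
    chromLens <- GenomeInfoDb::seqlengths(assembly)

    ## -- substream 1: fragment lengths and non-overlapping placement -------
    placed <- withSeed(subSeed(cfg$seed, 101), {
        w <- round(rlnorm(cfg$nPirs, cfg$pirLengthMeanlog,
                          cfg$pirLengthSdlog))
        w <- pmin(pmax(w, cfg$pirLengthRange[1]), cfg$pirLengthRange[2])
        gaps <- round(runif(cfg$nPirs, 500, 2500))
        list(w = w, gaps = gaps)
    })
    w <- placed$w
    margin <- cfg$jitter + 2   # keep sites and their jitter inside bounds
    chromIdx <- integer(cfg$nPirs); start0 <- numeric(cfg$nPirs)
    cur <- 1L; pos <- 1000
    for (i in seq_len(cfg$nPirs)) {
        if (pos + w[i] + margin > chromLens[cur]) {
            cur <- cur + 1L
            if (cur > cfg$nChroms)
                stop("assembly too small for ", cfg$nPirs,
                     " PIRs; increase chromLength or nChroms")
            pos <- 1000
        }
        chromIdx[i] <- cur
        start0[i] <- pos
        pos <- pos + w[i] + placed$gaps[i]
    }
    chrom <- paste0("chr", chromIdx)
    end0 <- start0 + w
    pirs <- makeTrack(chrom, start0, end0, assembly = assembly,
                      trackName = "PIRs")
    # placement is already position-sorted, so row order is preserved
    stopifnot(identical(GenomicRanges::start(pirs) - 1L, as.integer(start0)))

    l10 <- log10(w)

    ## -- substream 2: RNA flags and contact pairs --------------------------
    rnaSim <- withSeed(subSeed(cfg$seed, 102), {
        pRna <- plogis(cfg$rnaIntercept + cfg$rnaLengthSlope * l10)
        hasRna <- runif(cfg$nPirs) < pRna
        idx <- which(hasRna)
        nC <- 1L + rpois(length(idx), 0.5)
        pirI <- rep(idx, nC)
        dw <- pmin(w[pirI] - 2, round(runif(length(pirI), 100, 500)))
        off <- floor(runif(length(pirI)) * (w[pirI] - dw - 1)) + 1
        dnaStart <- start0[pirI] + off
        rnaChrom <- paste0("chr", sample.int(cfg$nChroms, length(pirI),
                                             replace = TRUE))
        rnaStart <- floor(runif(length(pirI)) *
                              (cfg$chromLength - 600)) + 1
        list(hasRna = hasRna,
             contacts = data.frame(
                 rna_chrom = rnaChrom, rna_start = as.integer(rnaStart),
                 rna_end = as.integer(rnaStart + 500),
                 rna_name = paste0("RNA", pirI),
                 dna_chrom = chrom[pirI], dna_start = as.integer(dnaStart),
                 dna_end = as.integer(dnaStart + dw),
                 stringsAsFactors = FALSE))
    })
    hasRna <- rnaSim$hasRna
    contacts <- rnaSim$contacts

    ## -- substream 3: binding-site flags, placements, replicate tracks -----
    tfbsSim <- withSeed(subSeed(cfg$seed, 103), {
        pSite <- plogis(cfg$tfbsIntercept + cfg$tfbsLogOr * hasRna +
                            cfg$tfbsLengthSlope * l10)
        hasTfbs <- runif(cfg$nPirs) < pSite
        idx <- which(hasTfbs)
        # one site per flagged PIR, >= jitter+1 bp from the fragment edges
        slack <- w[idx] - cfg$tfbsWidth - 2 * (cfg$jitter + 1)
        off <- cfg$jitter + 1 + floor(runif(length(idx)) * (slack + 1))
        siteStart <- start0[idx] + off
        siteEnd <- siteStart + cfg$tfbsWidth
        # background sites in the gaps between PIRs (never near a PIR)
        nBg <- round(cfg$backgroundRate * length(idx))
        cand <- 4L * nBg
        bgChrom <- sample.int(cfg$nChroms, cand, replace = TRUE)
        bgStart <- floor(runif(cand) *
                             (cfg$chromLength - cfg$tfbsWidth -
                                  2 * margin)) + margin
        bg <- GenomicRanges::GRanges(
            seqnames = factor(paste0("chr", bgChrom),
                              levels = GenomeInfoDb::seqnames(assembly)),
            ranges = IRanges::IRanges(start = bgStart + 1,
                                      width = cfg$tfbsWidth))
        wide <- GenomicRanges::resize(pirs,
                                      GenomicRanges::width(pirs) +
                                          2 * (cfg$jitter + 2),
                                      fix = "center")
        keep <- which(!IRanges::overlapsAny(bg, wide))[seq_len(nBg)]
        keep <- keep[!is.na(keep)]
        bgKeep <- bg[keep]
        trueSites <- data.frame(
            chrom = c(chrom[idx],
                      as.character(GenomicRanges::seqnames(bgKeep))),
            start = c(siteStart, GenomicRanges::start(bgKeep) - 1),
            end = c(siteEnd, GenomicRanges::end(bgKeep)))
        tracks <- lapply(seq_len(cfg$nTracks), function(t) {
            ds <- sample(seq(-cfg$jitter, cfg$jitter),
                         nrow(trueSites), replace = TRUE)
            de <- sample(seq(-cfg$jitter, cfg$jitter),
                         nrow(trueSites), replace = TRUE)
            makeTrack(trueSites$chrom,
                      pmax(trueSites$start + ds, 0),
                      pmin(trueSites$end + de, cfg$chromLength),
                      assembly = assembly,
                      trackName = sprintf("%s_track%d", cfg$tfbsFactor, t))
        })
        list(hasTfbs = hasTfbs, trueSites = trueSites, tracks = tracks)
    })
    hasTfbs <- tfbsSim$hasTfbs

    ## -- substream 4: genes and bait promoters ------------------------------
    geneSim <- withSeed(subSeed(cfg$seed, 104), {
        nGenesPir <- 1L + rpois(cfg$nPirs, cfg$genesPerPirLambda)
        pirI <- rep(seq_len(cfg$nPirs), nGenesPir)
        gene <- sprintf("G%05d", sample.int(cfg$nGenes, length(pirI),
                                            replace = TRUE))
        baitStart <- floor(runif(length(pirI)) *
                               (cfg$chromLength - 3000)) + 1
        pchic <- data.frame(
            bait_chrom = chrom[pirI], bait_start = as.integer(baitStart),
            bait_end = as.integer(baitStart + 1500), bait_genes = gene,
            pir_chrom = chrom[pirI], pir_start = as.integer(start0[pirI]),
            pir_end = as.integer(end0[pirI]), stringsAsFactors = FALSE)
        list(pirI = pirI, gene = gene, pchic = pchic)
    })
    genes <- lapply(split(geneSim$gene, geneSim$pirI)[
        as.character(seq_len(cfg$nPirs))],
        function(g) sort(unique(g)))
    S4Vectors::mcols(pirs)$genes <- unname(genes)

    ## gene-level planted category: strongest category among contacted PIRs
    cat4 <- ifelse(hasRna & hasTfbs, "RNA_and_TFBS",
                   ifelse(hasRna, "RNA_only",
                          ifelse(hasTfbs, "TFBS_only", "neither")))
    rankOf <- c(RNA_and_TFBS = 4, RNA_only = 3, TFBS_only = 2, neither = 1)
    geneCat <- vapply(split(cat4[geneSim$pirI], geneSim$gene),
                      function(cc) cc[which.max(rankOf[cc])], character(1))

    ## -- substream 5: expression -------------------------------------------
    tpm <- withSeed(subSeed(cfg$seed, 105), {
        gsym <- names(geneCat)
        base <- rlnorm(length(gsym), cfg$exprMeanlog, cfg$exprSdlog)
        true <- base * cfg$exprEffects[geneCat]
        k <- cfg$transcriptsPerGene
        prop <- matrix(stats::rgamma(length(gsym) * k, shape = 1),
                       ncol = k)
        prop <- prop / rowSums(prop)
        txTrue <- as.vector(t(prop * true))
        txId <- paste0(rep(gsym, each = k), ".t", seq_len(k))
        reps <- lapply(1:2, function(r)
            data.frame(transcript_id = txId,
                       gene_symbol = rep(gsym, each = k),
                       tpm = txTrue * exp(rnorm(length(txTrue), 0,
                                                cfg$exprNoiseSdlog)),
                       stringsAsFactors = FALSE))
        list(reps = reps, trueTpm = stats::setNames(true, gsym))
    })

    ## -- substream 6: qPCR --------------------------------------------------
    ct <- withSeed(subSeed(cfg$seed, 106), {
        rows <- list()
        addAssay <- function(target, baseCt, shiftByGroup) {
            for (grp in names(shiftByGroup))
                for (s in seq_len(cfg$nQpcrSamples)) {
                    sampleEff <- rnorm(1, 0, 0.05)
                    for (r in 1:3)
                        rows[[length(rows) + 1L]] <<- data.frame(
                            sample_id = sprintf("%s_s%d", grp, s),
                            group = grp, target = target, replicate = r,
                            ct = baseCt + shiftByGroup[[grp]] + sampleEff +
                                rnorm(1, 0, cfg$qpcrNoiseSd),
                            stringsAsFactors = FALSE)
                }
        }
        ## expression assays: reference IPO8 flat; targets shifted by
        ## -log2(fold) in the test group relative to control
        addAssay("IPO8", 20, list(control = 0, deletion = 0))
        for (g in names(cfg$qpcrFolds))
            addAssay(g, 25, list(control = 0,
                                 deletion = -log2(cfg$qpcrFolds[[g]])))
        ## 3C assays: ERCC3 junction as internal control
        addAssay("ERCC3", 24, list(control = 0, deletion = 0))
        addAssay("MSX1_PIR_junction", 28,
                 list(control = 0, deletion = -log2(cfg$qpcr3cFold)))
        do.call(rbind, rows)
    })

    rnaRegions <- makeTrack(contacts$dna_chrom, contacts$dna_start,
                            contacts$dna_end, assembly = assembly,
                            trackName = "RNA-contacted DNA regions")
    rnaRegions <- unique(rnaRegions)

    truth <- list(
        seed = cfg$seed,
        plantedOr = exp(cfg$tfbsLogOr),
        plantedLogOr = cfg$tfbsLogOr,
        nPirs = cfg$nPirs,
        nRnaPirs = sum(hasRna),
        nTfbsPirs = sum(hasTfbs),
        exprEffects = as.list(cfg$exprEffects),
        qpcrFolds = as.list(cfg$qpcrFolds),
        qpcr3cFold = cfg$qpcr3cFold,
        tfbsFactor = cfg$tfbsFactor)

    list(assembly = assembly, pirs = pirs, hasRna = hasRna,
         hasTfbs = hasTfbs,
         tfbsTrue = makeTrack(tfbsSim$trueSites$chrom,
                              tfbsSim$trueSites$start,
                              tfbsSim$trueSites$end, assembly = assembly,
                              trackName = "true sites"),
         tracks = tfbsSim$tracks,
         rnaRegions = rnaRegions, contacts = contacts,
         pchic = geneSim$pchic, tpm = tpm$reps, trueTpm = tpm$trueTpm,
         geneCategory = geneCat, ct = ct, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Serialises \code{\link{simulatePirData}} output into exactly the
#' formats the pipeline consumes: \code{chrom.sizes}, \code{pchic.tsv}
#' (with a handful of interchromosomal decoy rows), \code{margi.tsv} (with
#' duplicate pairs and unplaced-scaffold rows that the loader must
#' remove), one BED file per replicate binding-site track,
#' \code{tpm_rep1.tsv}/\code{tpm_rep2.tsv}, \code{ct.csv} and
#' \code{truth.json}. Byte-identical for identical config and seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of written paths plus the ground truth.
#' @export
generateDataset <- function(config, outdir) {
    sim <- simulatePirData(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)

    writeChromSizes(sim$assembly, p("chrom.sizes"))

    ## pchic with interchromosomal decoys appended (loader drops them)
    pchic <- sim$pchic
    decoy <- withSeed(subSeed(config$seed, 107), {
        n <- min(20L, nrow(pchic))
        idx <- sample.int(nrow(pchic), n)
        d <- pchic[idx, , drop = FALSE]
        other <- paste0("chr", (match(d$bait_chrom,
                                      paste0("chr",
                                             seq_len(config$nChroms))) %%
                                    config$nChroms) + 1L)
        d$bait_chrom <- other
        d
    })
    writeTsv(rbind(pchic, decoy), p("pchic.tsv"))

    ## margi with duplicate pairs and unplaced-scaffold rows appended
    contacts <- sim$contacts
    extra <- withSeed(subSeed(config$seed, 108), {
        dup <- contacts[sample.int(nrow(contacts),
                                   min(25L, nrow(contacts))), , drop = FALSE]
        sc <- contacts[sample.int(nrow(contacts),
                                  min(10L, nrow(contacts))), , drop = FALSE]
        sc$dna_chrom <- "chrUn_gl000220"
        rbind(dup, sc)
    })
    writeTsv(rbind(contacts, extra), p("margi.tsv"))

    trackPaths <- vapply(seq_along(sim$tracks), function(t) {
        f <- p(sprintf("tfbs_%s_track%d.bed", config$tfbsFactor, t))
        writeBed(sim$tracks[[t]], f)
        f
    }, character(1))

    writeTsv(sim$tpm[[1]], p("tpm_rep1.tsv"))
    writeTsv(sim$tpm[[2]], p("tpm_rep2.tsv"))
    write.table(sim$ct, p("ct.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    writeReportJson(sim$truth, p("truth.json"))

    invisible(list(paths = c(p("chrom.sizes"), p("pchic.tsv"),
                             p("margi.tsv"), trackPaths,
                             p("tpm_rep1.tsv"), p("tpm_rep2.tsv"),
                             p("ct.csv"), p("truth.json")),
                   truth = sim$truth))
}
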