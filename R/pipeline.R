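#' Read and validate a pipeline configuration
#'
#' Configuration is one declarative YAML file; relative paths are resolved
#' against the config file's directory. Recognised keys: \code{seed},
#' \code{output_dir}, \code{assembly}, \code{pchic}, \code{margi},
#' \code{factors} (map factor -> list with \code{tracks}), \code{n_perm},
#' \code{covariate} (\code{log10-length}/\code{raw-length}/\code{none}),
#' \code{direction} (\code{tfbs-on-rna}/\code{rna-on-tfbs}),
#' \code{consensus_rule} (\code{consensus}/\code{each-track}),
#' \code{expression} (\code{tpm} file list, \code{factor},
#' \code{compare} pair of category names), \code{qpcr} (\code{ct},
#' \code{reference}, \code{control_group}, \code{test_group},
#' \code{targets}, optional \code{junction}/\code{junction_reference}),
#' and \code{simulate} (arguments for \code{\link{syntheticConfig}}).
#' Values in \code{overrides} replace file values (the command-line entry
#' point uses this for its flags).
#'
#' @param path path to the YAML file.
#' @param overrides named list of overriding values.
#' @return the config as a list, with \code{dir}, \code{path} and
#'   \code{hash} (md5 of the file) attached.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
    if (is.null(cfg$seed)) stop("config error: 'seed' is required")
    if (!is.null(cfg$n_perm) && cfg$n_perm < 1)
        stop("config error: n_perm must be >= 1")
    cfg$covariate <- cfg$covariate %||% "log10-length"
    cfg$direction <- cfg$direction %||% "tfbs-on-rna"
    cfg$consensus_rule <- cfg$consensus_rule %||% "consensus"
    cfg$n_perm <- cfg$n_perm %||% 1000L
    cfg$output_dir <- cfg$output_dir %||% "rnapir_out"
    cfg$dir <- dirname(normalizePath(path))
    cfg$path <- path
    cfg$hash <- unname(tools::md5sum(path))
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfgPath <- function(cfg, p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(cfg$dir, p)
}

asConfig <- function(config, overrides = list()) {
    if (is.character(config)) readPipelineConfig(config, overrides)
    else config
}

withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

reportMeta <- function(cfg) {
    list(config = cfg$path %||% NA, config_hash = cfg$hash %||% NA,
         seed = cfg$seed,
         version = as.character(utils::packageVersion("rnapir")))
}

#' Generate a synthetic dataset from a pipeline config
#'
#' Thin wrapper over \code{\link{generateDataset}}: the \code{simulate}
#' section of the config supplies \code{\link{syntheticConfig}} arguments
#' (the config-level \code{seed} is used), and files are written to
#' \code{output_dir}.
#'
#' @param config path to a YAML config or a config list.
#' @param overrides named list overriding config values.
#' @return invisibly, the \code{\link{generateDataset}} result.
#' @export
runSimulate <- function(config, overrides = list()) {
    cfg <- asConfig(config, overrides)
    withStage("simulate", {
        args <- cfg$simulate %||% list()
        args$seed <- cfg$seed
        simCfg <- do.call(syntheticConfig, args)
        out <- cfgPath(cfg, cfg$output_dir)
        logMsg("simulate: writing synthetic dataset to ", out)
        generateDataset(simCfg, out)
    })
}

# Shared load/classify/annotate front end for the analysis commands.
loadAndClassify <- function(cfg) {
    assembly <- withStage("assembly",
        readChromSizes(cfgPath(cfg, cfg$assembly)))
    pch <- withStage("load-pchic",
        loadPchic(cfgPath(cfg, cfg$pchic), assembly = assembly))
    mar <- withStage("load-margi",
        loadMargi(cfgPath(cfg, cfg$margi), assembly = assembly))
    pirSet <- withStage("classify", classifyPirs(pch$pirs, mar$dnaRegions))
    tracks <- withStage("read-tracks", lapply(cfg$factors, function(f)
        lapply(f$tracks, function(tp)
            readBed(cfgPath(cfg, tp), assembly = assembly))))
    for (factor in names(tracks))
        pirSet <- withStage("annotate",
            annotateTfbs(pirSet, tracks[[factor]], factor = factor,
                         rule = cfg$consensus_rule))
    list(assembly = assembly, pirSet = pirSet, tracks = tracks,
         nInterchromosomal = pch$nInterchromosomal,
         nRemovedScaffold = mar$nRemovedScaffold,
         nContacts = nrow(mar$contacts),
         nDnaRegions = length(mar$dnaRegions))
}

#' Run the binding-site enrichment analysis end to end
#'
#' Loads the interaction and contact tables, classifies PIRs by RNA
#' overlap, annotates each configured factor's consensus sites, and for
#' each factor reports the contingency table, the covariate-adjusted
#' logistic-regression odds ratio with Wald CI and p-value, and the
#' shuffled-interval permutation p-value. Gene lists per category are
#' exported alongside. Deterministic given the config seed.
#'
#' @param config path to a YAML config or a config list.
#' @param overrides named list overriding config values.
#' @return invisibly, the report list (also written to
#'   \code{output_dir/enrichment_report.json} and a TSV summary).
#' @export
runEnrichment <- function(config, overrides = list()) {
    cfg <- asConfig(config, overrides)
    loaded <- loadAndClassify(cfg)
    pirSet <- loaded$pirSet
    out <- cfgPath(cfg, cfg$output_dir)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)

    rna <- hasRna(pirSet)
    logMsg("enrich: ", sum(rna), " RNA-PIRs / ", sum(!rna),
           " nonRNA-PIRs")
    factors <- names(cfg$factors)
    perFactor <- lapply(factors, function(factor) {
        counts <- buildContingency(pirSet, factor)
        enr <- withStage("regression",
            enrichmentTest(pirSet, factor, covariate = cfg$covariate,
                           direction = cfg$direction))
        perm <- withStage("permutation",
            permutationEnrichment(
                pirSet, loaded$tracks[[factor]], loaded$assembly,
                nPerm = cfg$n_perm, seed = cfg$seed,
                covariate = cfg$covariate, direction = cfg$direction,
                factor = factor))
        lists <- geneListsByCategory(pirSet, factor)
        writeGeneLists(lists, file.path(out, paste0("genes_", factor)))
        logMsg("enrich ", factor, ": OR = ", signif(oddsRatio(enr), 4),
               ", permutation P ", formatPermP(perm$permutation))
        list(factor = factor,
             counts = counts[c("a", "b", "c", "d", "pctRnaTfbs",
                               "pctNonrnaTfbs", "crudeOr")],
             beta = enr@beta, se = enr@se, or = oddsRatio(enr),
             ci_low = enr@ciLow, ci_high = enr@ciHigh,
             p_wald = pValue(enr),
             covariate = cfg$covariate, direction = cfg$direction,
             n_perm = perm$permutation@nPerm,
             r_lower = perm$permutation@rLower,
             p_perm = perm$permutation@pPerm,
             p_perm_printed = formatPermP(perm$permutation),
             gene_list_sizes = lapply(lists, length))
    })
    names(perFactor) <- factors
    report <- c(reportMeta(cfg),
                list(n_pirs = length(pirSet),
                     n_rna_pirs = sum(rna), n_nonrna_pirs = sum(!rna),
                     n_interchromosomal_removed =
                         loaded$nInterchromosomal,
                     n_scaffold_removed = loaded$nRemovedScaffold,
                     n_unique_contacts = loaded$nContacts,
                     n_unique_dna_regions = loaded$nDnaRegions,
                     factors = perFactor))
    writeReportJson(report, file.path(out, "enrichment_report.json"))
    writeTsv(do.call(rbind, lapply(perFactor, function(f)
        data.frame(factor = f$factor, a = f$counts$a, b = f$counts$b,
                   c = f$counts$c, d = f$counts$d,
                   pct_rna = f$counts$pctRnaTfbs,
                   pct_nonrna = f$counts$pctNonrnaTfbs,
                   or = f$or, ci_low = f$ci_low, ci_high = f$ci_high,
                   p_wald = f$p_wald, p_perm = f$p_perm))),
        file.path(out, "enrichment_summary.tsv"))
    invisible(report)
}

#' Compare expression between PIR categories
#'
#' Aggregates replicate transcript TPM tables to gene level, attaches the
#' genes of each PIR category for the configured factor, and compares the
#' two configured categories (default: RNA-PIRs with sites versus non-RNA
#' PIRs with sites) with a two-sided Mann-Whitney test.
#'
#' @param config path to a YAML config or a config list.
#' @param overrides named list overriding config values.
#' @return invisibly, the report list (also written to
#'   \code{output_dir/expression_report.json}).
#' @export
runExpression <- function(config, overrides = list()) {
    cfg <- asConfig(config, overrides)
    if (is.null(cfg$expression))
        stop("config error: no 'expression' section")
    loaded <- loadAndClassify(cfg)
    out <- cfgPath(cfg, cfg$output_dir)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ex <- cfg$expression
    factor <- ex$factor %||% names(cfg$factors)[1]
    lists <- geneListsByCategory(loaded$pirSet, factor)
    expr <- withStage("gene-tpm",
        geneTpm(lapply(ex$tpm, function(f) readTpm(cfgPath(cfg, f)))))
    catExpr <- withStage("category-expression",
        categoryExpression(lists, expr))
    compare <- ex$compare %||%
        c(paste0("RNA_and_", factor), paste0(factor, "_only"))
    if (!all(compare %in% names(catExpr$tpms)))
        stop("config error: unknown category in 'compare': ",
             paste(setdiff(compare, names(catExpr$tpms)), collapse = ", "))
    mw <- mannWhitney(catExpr$tpms[[compare[1]]],
                      catExpr$tpms[[compare[2]]])
    logMsg("expression: mean TPM ", compare[1], " = ",
           signif(mean(catExpr$tpms[[compare[1]]]), 4), " vs ",
           compare[2], " = ",
           signif(mean(catExpr$tpms[[compare[2]]]), 4),
           " (Mann-Whitney P = ", signif(mw$p, 3), ")")
    report <- c(reportMeta(cfg),
                list(factor = factor,
                     categories = catExpr$summary,
                     compare = as.list(stats::setNames(
                         lapply(compare, function(cc)
                             mean(catExpr$tpms[[cc]])), compare)),
                     mann_whitney_U = mw$U, mann_whitney_p = mw$p,
                     mann_whitney_method = mw$method))
    writeReportJson(report, file.path(out, "expression_report.json"))
    writeTsv(catExpr$summary, file.path(out, "expression_summary.tsv"))
    invisible(report)
}

#' Quantify qPCR and 3C-qPCR readouts
#'
#' Applies the 2^-ddCt method to every configured expression target
#' (against the internal reference assay) and, when configured, to the 3C
#' ligation junction (against its internal-control junction). P-values are
#' Welch t-tests on dCt values, Bonferroni-adjusted across the targets.
#'
#' @param config path to a YAML config or a config list.
#' @param overrides named list overriding config values.
#' @return invisibly, the report list (also written to
#'   \code{output_dir/qpcr_report.json}).
#' @export
runQpcr <- function(config, overrides = list()) {
    cfg <- asConfig(config, overrides)
    if (is.null(cfg$qpcr)) stop("config error: no 'qpcr' section")
    q <- cfg$qpcr
    out <- cfgPath(cfg, cfg$output_dir)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ct <- withStage("read-ct", readCt(cfgPath(cfg, q$ct)))
    m <- length(q$targets)
    res <- lapply(q$targets, function(tg) withStage("ddct",
        deltaDeltaCt(ct, tg, q$reference %||% "IPO8",
                     q$control_group, q$test_group, m = m)))
    names(res) <- q$targets
    if (!is.null(q$junction))
        res[[q$junction]] <- withStage("3c",
            quantify3c(ct, q$junction,
                       reference = q$junction_reference %||% "ERCC3",
                       controlGroup = q$control_group,
                       testGroup = q$test_group))
    tab <- do.call(rbind, lapply(res, function(r)
        data.frame(target = r$target, reference = r$reference,
                   ddct = r$ddct, fold = r$fold, se_ddct = r$seDdct,
                   fold_low = r$foldInterval[["low"]],
                   fold_high = r$foldInterval[["high"]],
                   p_raw = r$pRaw, p_adj = r$pAdj)))
    for (r in res)
        logMsg("qpcr ", r$target, ": fold = ", signif(r$fold, 4),
               " (adj. P = ", signif(r$pAdj, 3), ")")
    report <- c(reportMeta(cfg), list(results = res))
    writeReportJson(report, file.path(out, "qpcr_report.json"))
    writeTsv(tab, file.path(out, "qpcr_summary.tsv"))
    invisible(report)
}

#' Run every configured analysis and aggregate the reports
#'
#' @param config path to a YAML config or a config list.
#' @param overrides named list overriding config values.
#' @return invisibly, a list with \code{enrichment}, \code{expression}
#'   and \code{qpcr} reports (sections absent from the config are
#'   skipped), also written to \code{output_dir/report.json}.
#' @export
runReport <- function(config, overrides = list()) {
    cfg <- asConfig(config, overrides)
    out <- cfgPath(cfg, cfg$output_dir)
    report <- list(enrichment = runEnrichment(cfg))
    if (!is.null(cfg$expression)) report$expression <- runExpression(cfg)
    if (!is.null(cfg$qpcr)) report$qpcr <- runQpcr(cfg)
    writeReportJson(c(reportMeta(cfg), report),
                    file.path(out, "report.json"))
    invisible(report)
}
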