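writePchic <- function(rows) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(paste("bait_chrom", "bait_start", "bait_end", "bait_genes",
                       "pir_chrom", "pir_start", "pir_end", sep = "\t"),
                 rows), f)
    f
}

writeMargi <- function(rows) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(paste("rna_chrom", "rna_start", "rna_end",
                       "dna_chrom", "dna_start", "dna_end", sep = "\t"),
                 rows), f)
    f
}

test_that("promoter-interaction loading drops interchromosomal rows and dedups PIRs with gene union", {
    f <- writePchic(c(
        "chr1\t100\t200\tGENE1\tchr1\t5000\t6000",
        "chr1\t300\t400\tGENE2\tchr1\t5000\t6000",   # same PIR, 2nd bait
        "chr1\t100\t200\tGENE1\tchr2\t5000\t6000",   # interchromosomal
        "chr2\t100\t200\tGENE3\tchr2\t9000\t9500",
        "chr1\t700\t800\tGENE4;GENE5\tchr1\t8000\t8800",
        "chr1\t100\t200\tGENE1\tchr1\t5000\t6000"))  # exact duplicate row
    res <- loadPchic(f)
    expect_equal(res$nInterchromosomal, 1)
    expect_length(res$pirs, 3)
    genes <- S4Vectors::mcols(res$pirs)$genes
    key <- paste0(GenomicRanges::seqnames(res$pirs), ":",
                  GenomicRanges::start(res$pirs) - 1)
    expect_setequal(genes[[which(key == "chr1:5000")]], c("GENE1", "GENE2"))
    expect_setequal(genes[[which(key == "chr1:8000")]], c("GENE4", "GENE5"))
    expect_setequal(genes[[which(key == "chr2:9000")]], "GENE3")
    # row order never matters
    res2 <- loadPchic(writePchic(rev(readLines(f)[-1])))
    expect_identical(grToBed(res$pirs), grToBed(res2$pirs))

    expect_error(loadPchic(writeMargi("chr1\t1\t2\tchr1\t3\t4")),
                 "required column")
})

test_that("contact loading removes unplaced scaffolds and collapses duplicate pairs", {
    f <- writeMargi(c(
        "chr1\t100\t600\tchr2\t1000\t1200",
        "chr1\t100\t600\tchr2\t1000\t1200",          # duplicate pair
        "chr1\t900\t1400\tchr2\t1000\t1200",         # same DNA region
        "chr3\t100\t600\tchr3\t5000\t5400",
        "chr1\t100\t600\tchrUn_gl000220\t10\t200"))  # unplaced
    res <- loadMargi(f)
    expect_equal(nrow(res$contacts), 3)   # unique interactions
    expect_length(res$dnaRegions, 2)      # unique DNA regions
    expect_equal(res$nRemovedScaffold, 1)
    expect_equal(res$nDuplicates, 1)

    # cleaning an already-clean file changes nothing
    clean <- writeMargi(with(res$contacts,
        paste(rnaChrom, rnaStart, rnaEnd,
              dnaChrom, dnaStart, dnaEnd, sep = "\t")))
    res2 <- loadMargi(clean)
    expect_equal(res2$nRemovedScaffold, 0)
    expect_equal(res2$nDuplicates, 0)
    expect_identical(grToBed(res2$dnaRegions), grToBed(res$dnaRegions))

    # "_random" suffixed names are scaffolds too
    f3 <- writeMargi(c("chr1\t1\t100\tchr1_gl000191_random\t5\t50",
                       "chr1\t1\t100\tchr1\t500\t600"))
    expect_equal(loadMargi(f3)$nRemovedScaffold, 1)
})

test_that("classification and annotation are idempotent and match planted flags on a fixture", {
    d <- tempfile()
    makeWorkedFixture(d)
    asm <- readChromSizes(file.path(d, "chrom.sizes"))
    pch <- loadPchic(file.path(d, "pchic.tsv"), assembly = asm)
    mar <- loadMargi(file.path(d, "margi.tsv"), assembly = asm)
    ps <- classifyPirs(pch$pirs, mar$dnaRegions)
    expect_length(ps, 12)
    # hand enumeration: PIRs 1,2,5 on chr1 and 7,9,11 (chr2) contact RNA
    expect_identical(hasRna(ps),
                     c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                       TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
    tracks <- lapply(1:3, function(t)
        readBed(file.path(d, sprintf("tfbs_CTCF_track%d.bed", t)),
                assembly = asm))
    ps <- annotateTfbs(ps, tracks, "CTCF")
    expect_identical(unname(hasTfbs(ps, "CTCF")),
                     c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
                       FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
    # idempotence
    ps2 <- annotateTfbs(classifyPirs(pch$pirs, mar$dnaRegions), tracks, "CTCF")
    expect_identical(hasTfbs(ps2, "CTCF"), hasTfbs(ps, "CTCF"))

    # empty RNA regions or empty consensus give all-FALSE flags
    none <- classifyPirs(pch$pirs, GenomicRanges::GRanges())
    expect_false(any(hasRna(none)))
    noSites <- annotateTfbs(ps, GenomicRanges::GRanges(), "YY1")
    expect_false(any(hasTfbs(noSites, "YY1")))

    expect_error(annotateTfbs(ps, tracks, "bad factor!"), "unknown factor")
    expect_error(hasTfbs(ps, "GATA4"), "not been annotated")
})

test_that("the each-track agreement rule differs from per-base consensus where tracks disagree in position", {
    asm <- toyAssembly()
    pirs <- makeTrack("chr1", 1000, 2000, assembly = asm)
    S4Vectors::mcols(pirs)$genes <- list("G1")
    ps <- classifyPirs(pirs, GenomicRanges::GRanges())
    # two tracks overlap the PIR at disjoint positions: no common base
    t1 <- makeTrack("chr1", 1100, 1200, assembly = asm)
    t2 <- makeTrack("chr1", 1500, 1600, assembly = asm)
    cons <- annotateTfbs(ps, list(t1, t2), "CTCF", rule = "consensus")
    each <- annotateTfbs(ps, list(t1, t2), "CTCF", rule = "each-track")
    expect_false(hasTfbs(cons, "CTCF"))
    expect_true(hasTfbs(each, "CTCF"))
})

test_that("contingency cells, percentages and crude OR follow their definitions", {
    d <- tempfile()
    makeWorkedFixture(d)
    asm <- readChromSizes(file.path(d, "chrom.sizes"))
    ps <- classifyPirs(loadPchic(file.path(d, "pchic.tsv"), assembly = asm)$pirs,
                       loadMargi(file.path(d, "margi.tsv"), assembly = asm)$dnaRegions)
    ps <- annotateTfbs(ps, lapply(1:3, function(t)
        readBed(file.path(d, sprintf("tfbs_CTCF_track%d.bed", t)),
                assembly = asm)), "CTCF")
    ct <- buildContingency(ps, "CTCF")
    expect_equal(ct[c("a", "b", "c", "d")], list(a = 3, b = 3, c = 2, d = 4))
    expect_equal(ct$pctRnaTfbs, 50)
    expect_equal(ct$pctNonrnaTfbs, 100 * 2 / 6)
    expect_equal(ct$crudeOr, 2)
    expect_equal(ct$a + ct$b + ct$c + ct$d, length(ps))
    expect_error(buildContingency(ps, "YY1"), "not been annotated")

    # crude OR closed form on a synthetic flag layout: (10*40)/(20*30)
    flags <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = seq(1, by = 200, length.out = 100),
                         width = 100))
    S4Vectors::mcols(flags)$genes <- replicate(100, character(0),
                                               simplify = FALSE)
    S4Vectors::mcols(flags)$hasRna <- rep(c(TRUE, FALSE), c(30, 70))
    S4Vectors::mcols(flags)$hasX <- rep(c(TRUE, FALSE, TRUE, FALSE),
                                        c(10, 20, 30, 40))
    obj <- methods::new("PirSet", ranges = flags, factors = "X")
    expect_equal(buildContingency(obj, "X")$crudeOr, 2 / 3,
                 tolerance = 1e-12)
})

test_that("gene lists dedup within category and allow genes in several categories", {
    d <- tempfile()
    makeWorkedFixture(d)
    asm <- readChromSizes(file.path(d, "chrom.sizes"))
    ps <- classifyPirs(loadPchic(file.path(d, "pchic.tsv"), assembly = asm)$pirs,
                       loadMargi(file.path(d, "margi.tsv"), assembly = asm)$dnaRegions)
    ps <- annotateTfbs(ps, lapply(1:3, function(t)
        readBed(file.path(d, sprintf("tfbs_CTCF_track%d.bed", t)),
                assembly = asm)), "CTCF")
    lists <- geneListsByCategory(ps, "CTCF")
    expect_setequal(lists$RNA_and_CTCF, c("G1", "G5", "G6", "G9"))
    expect_setequal(lists$RNA_only, c("G2", "G7", "G11"))
    expect_setequal(lists$CTCF_only, c("G1", "G3"))  # G1 sits in two lists
    expect_setequal(lists$neither, c("G4", "G8", "G10", "G12"))
    expect_false(anyDuplicated(lists$RNA_and_CTCF) > 0)

    paths <- writeGeneLists(lists, tempfile())
    expect_identical(readLines(paths[["RNA_and_CTCF"]]),
                     lists$RNA_and_CTCF)
})
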