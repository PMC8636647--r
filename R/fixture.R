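#' Write the 12-PIR worked example dataset
#'
#' A tiny, fully hand-written dataset in which every flag can be checked by
#' eye; it is used in the documentation and in golden tests. Layout (BED
#' coordinates; R = overlaps an RNA-contacted region, C = overlaps the
#' CTCF consensus):
#'
#' \preformatted{
#'  PIR  coords               genes   R C
#'   1   chr1:1000-3000       G1      + +
#'   2   chr1:5000-7000       G2      + -
#'   3   chr1:9000-11000      G3      - +
#'   4   chr1:13000-15000     G4      - -
#'   5   chr1:17000-20000     G5,G6   + +
#'   6   chr1:22000-24000     G1      - +
#'   7   chr2:1000-3000       G7      + -   (1-bp contact overlap)
#'   8   chr2:5000-8000       G8      - -   (contact abuts at 8000)
#'   9   chr2:10000-12000     G9      + +
#'  10   chr2:14000-16000     G10     - -
#'  11   chr2:18000-21000     G11     + -
#'  12   chr2:23000-25000     G12     - -
#' }
#'
#' Hence the CTCF contingency cells are a = 3 (PIRs 1, 5, 9), b = 3
#' (2, 7, 11), c = 2 (3, 6), d = 4 (4, 8, 10, 12); 50\% of RNA-PIRs and
#' 33.3\% of non-RNA PIRs carry sites, crude odds ratio 2. The three
#' replicate CTCF tracks are jittered copies (-5/0, 0/+5, +5/-5 bp on
#' start/end) of six true 200-bp sites, so each consensus interval is the
#' true site shrunk by 5 bp on both sides. The promoter-interaction table
#' carries one interchromosomal decoy row and one duplicated row; the
#' contact table carries one duplicate pair and one \code{chrUn} scaffold
#' row. Gene TPMs are integers with per-category means 25
#' (\code{RNA_and_CTCF}), 8 (\code{RNA_only}), 8 (\code{CTCF_only}) and 2
#' (\code{neither}); the Ct table plants fold changes of exactly 2 (MSX1
#' expression and the MSX1 promoter-PIR 3C junction) and 0.25
#' (STX18AS1) in the deletion group.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
makeWorkedFixture <- function(dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)

    writeLines(c("chr1\t200000", "chr2\t200000"), p("chrom.sizes"))

    pir <- list(  # chrom, start, end, genes (one row per bait gene)
        c("chr1", 1000, 3000, "G1"),
        c("chr1", 5000, 7000, "G2"),
        c("chr1", 9000, 11000, "G3"),
        c("chr1", 13000, 15000, "G4"),
        c("chr1", 17000, 20000, "G5"),
        c("chr1", 17000, 20000, "G6"),
        c("chr1", 22000, 24000, "G1"),
        c("chr2", 1000, 3000, "G7"),
        c("chr2", 5000, 8000, "G8"),
        c("chr2", 10000, 12000, "G9"),
        c("chr2", 14000, 16000, "G10"),
        c("chr2", 18000, 21000, "G11"),
        c("chr2", 23000, 25000, "G12"),
        c("chr1", 1000, 3000, "G1"))          # duplicated row
    rows <- vapply(pir, function(r) {
        s <- as.numeric(r[2])
        sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                r[1], as.integer(s + 100000), as.integer(s + 101500),
                r[4], r[1], r[2], r[3])
    }, character(1))
    inter <- "chr1\t50000\t51500\tGX\tchr2\t40000\t42000"  # dropped
    writeLines(c(paste("bait_chrom", "bait_start", "bait_end", "bait_genes",
                       "pir_chrom", "pir_start", "pir_end", sep = "\t"),
                 rows, inter), p("pchic.tsv"))

    margi <- c(
        "chr1\t50000\t50500\tRNA1\tchr1\t1500\t1600",
        "chr1\t60000\t60500\tRNA2\tchr1\t6950\t7050",
        "chr1\t70000\t70500\tRNA3\tchr1\t17000\t17100",
        "chr2\t80000\t80500\tRNA4\tchr2\t2999\t3000",     # 1-bp overlap
        "chr2\t90000\t90500\tRNA5\tchr2\t11000\t11200",
        "chr2\t95000\t95500\tRNA6\tchr2\t18500\t18700",
        "chr2\t95000\t95500\tRNA6\tchr2\t18500\t18700",   # duplicate pair
        "chr2\t99000\t99500\tRNA7\tchr2\t8000\t8100",     # abuts PIR 8
        "chr1\t10000\t10500\tRNA8\tchrUn_gl000220\t100\t200")  # scaffold
    writeLines(c(paste("rna_chrom", "rna_start", "rna_end", "rna_name",
                       "dna_chrom", "dna_start", "dna_end", sep = "\t"),
                 margi), p("margi.tsv"))

    sites <- rbind(  # true 200-bp CTCF sites; last one is background
        c("chr1", 1500), c("chr1", 9500), c("chr1", 18000),
        c("chr1", 22500), c("chr2", 10500), c("chr1", 30000))
    s <- as.numeric(sites[, 2]); e <- s + 200
    jit <- list(c(-5, 0), c(0, 5), c(5, -5))
    for (t in 1:3) {
        writeLines(sprintf("%s\t%d\t%d", sites[, 1],
                           as.integer(s + jit[[t]][1]),
                           as.integer(e + jit[[t]][2])),
                   p(sprintf("tfbs_CTCF_track%d.bed", t)))
    }

    tpmHeader <- "transcript_id\tgene_symbol\ttpm"
    tx <- c("G1.t1 G1", "G1.t2 G1", "G2.t1 G2", "G3.t1 G3", "G4.t1 G4",
            "G5.t1 G5", "G6.t1 G6", "G7.t1 G7", "G8.t1 G8", "G9.t1 G9",
            "G10.t1 G10", "G11.t1 G11", "G12.t1 G12")
    rep1 <- c(3, 7, 6, 6, 1, 18, 30, 12, 2, 40, 3, 4, 2)
    rep2 <- c(3, 7, 10, 6, 1, 22, 30, 12, 2, 40, 3, 4, 2)
    for (r in 1:2) {
        v <- if (r == 1) rep1 else rep2
        writeLines(c(tpmHeader,
                     sprintf("%s\t%g", gsub(" ", "\t", tx), v)),
                   p(sprintf("tpm_rep%d.tsv", r)))
    }

    ctLine <- function(grp, s, target, ct)
        sprintf("%s_s%d,%s,%s,1,%g", grp, s, grp, target, ct)
    ct <- c("sample_id,group,target,replicate,ct")
    for (grp in c("control", "deletion")) for (s in 1:3) {
        d <- (s - 2) / 10   # -0.1, 0, +0.1 spread across samples
        ct <- c(ct,
            ctLine(grp, s, "IPO8", 20),
            ctLine(grp, s, "MSX1",
                   if (grp == "control") 25 + d else 24 + d),
            ctLine(grp, s, "STX18AS1",
                   if (grp == "control") 23 + d else 25 + d),
            ctLine(grp, s, "ERCC3", 24),
            ctLine(grp, s, "MSX1_PIR_junction",
                   if (grp == "control") 28 + d else 27 + d))
    }
    writeLines(ct, p("ct.csv"))

    files <- c("chrom.sizes", "pchic.tsv", "margi.tsv",
               sprintf("tfbs_CTCF_track%d.bed", 1:3),
               "tpm_rep1.tsv", "tpm_rep2.tsv", "ct.csv")
    invisible(stats::setNames(vapply(files, p, character(1)), files))
}
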