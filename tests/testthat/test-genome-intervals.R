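test_that("BED parsing handles valid lines, headers, dedup and round-trips", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("track name=demo", "# comment",
                 "chr1\t100\t200", "chr1\t150\t250", "chr2\t0\t50"), f)
    gr <- readBed(f)
    expect_length(gr, 3)
    expect_equal(as.character(GenomicRanges::seqnames(gr)),
                 c("chr1", "chr1", "chr2"))
    expect_equal(GenomicRanges::start(gr), c(101, 151, 1))  # 1-based internal
    expect_equal(GenomicRanges::end(gr), c(200, 250, 50))

    # duplicate collapse is on by default and off on request
    writeLines(c("chr1\t100\t200", "chr1\t100\t200"), f)
    expect_length(readBed(f, dedupe = TRUE), 1)
    expect_length(readBed(f, dedupe = FALSE), 2)

    # read -> write -> read round-trips exactly
    writeLines(c("chr2\t10\t40", "chr1\t5\t25", "chr1\t100\t130"), f)
    gr1 <- readBed(f)
    f2 <- tempfile(fileext = ".bed")
    writeBed(gr1, f2)
    gr2 <- readBed(f2)
    expect_identical(grToBed(gr1), grToBed(gr2))
})

test_that("malformed BED lines fail with the offending line number", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200", "chr1\t200\t200"), f)
    expect_error(readBed(f), "line 2.*empty interval")
    writeLines(c("chr1\t100\t200", "chr1\t-5\t50"), f)
    expect_error(readBed(f), "line 2.*malformed")
    writeLines(c("chr1\tabc\t200"), f)
    expect_error(readBed(f), "malformed")
    writeLines(c("chr1\t100"), f)
    expect_error(readBed(f), "fewer than 3")
})

test_that("assembly binding rejects unknown chromosomes and out-of-bound ends", {
    asm <- toyAssembly()
    f <- tempfile(fileext = ".bed")
    writeLines("chr9\t0\t100", f)
    expect_error(readBed(f, assembly = asm), "absent from assembly")
    writeLines("chr1\t9990\t10500", f)
    expect_error(readBed(f, assembly = asm), "exceeds chromosome length")
    writeLines("weird_scaffold\t0\t100", f)
    expect_warning(readBed(f), "non-canonical")
})

test_that("overlap uses the half-open convention: 1-bp contact counts, abutment does not", {
    q <- makeTrack("chr1", 100, 200)
    expect_true(overlapFlags(q, makeTrack("chr1", 199, 300)))
    expect_false(overlapFlags(q, makeTrack("chr1", 200, 300)))
    expect_false(suppressWarnings(   # tracks share no sequence levels
        overlapFlags(q, makeTrack("chr2", 100, 200))))
    expect_error(
        overlapFlags(GenomicRanges::GRanges(c("chr1", "chr1"),
                                            IRanges::IRanges(c(500, 10), c(600, 20))),
                     q),
        "not sorted")
})

test_that("overlap flags match the all-pairs brute-force oracle on random tracks", {
    asm <- toyAssembly()
    withr::with_seed(42, {
        for (rep in 1:5) {
            q <- randomBedTrack(200, asm)
            s <- randomBedTrack(300, asm)
            expect_identical(unname(overlapFlags(q$gr, s$gr)),
                             bruteOverlapFlags(grToBed(q$gr), s$df))
        }
    })
})

test_that("consensus equals the per-base oracle, shrinks monotonically and ignores track order", {
    expect_equal(
        grToBed(consensusIntervals(list(makeTrack("chr1", 0, 10),
                                        makeTrack("chr1", 5, 15)))),
        data.frame(chrom = "chr1", start = 5, end = 10,
                   stringsAsFactors = FALSE))
    # empty member annihilates the consensus
    empty <- GenomicRanges::GRanges()
    expect_length(consensusIntervals(list(makeTrack("chr1", 0, 10), empty)), 0)
    expect_error(consensusIntervals(list()), "non-empty")

    asm <- makeAssembly(c("chr1", "chr2"), c(1500, 1200))
    withr::with_seed(7, {
        for (rep in 1:4) {
            tracks <- lapply(1:5, function(i) randomBedTrack(15, asm, maxLen = 400))
            grs <- lapply(tracks, `[[`, "gr")
            cons <- consensusIntervals(grs)
            oracle <- perBaseConsensus(lapply(grs, grToBed), asm)
            got <- grToBed(cons)
            if (is.null(oracle)) {
                expect_length(cons, 0)
            } else {
                rownames(oracle) <- NULL
                expect_equal(got, oracle, ignore_attr = TRUE)
            }
            # order independence
            perm <- sample(length(grs))
            expect_identical(grToBed(consensusIntervals(grs[perm])), got)
            # adding a track never enlarges total coverage
            extra <- randomBedTrack(10, asm, maxLen = 300)$gr
            expect_lte(sum(GenomicRanges::width(
                consensusIntervals(c(grs, list(extra))))),
                sum(GenomicRanges::width(cons)))
        }
    })
})

test_that("shuffling preserves lengths, respects bounds and is seed-deterministic", {
    asm <- toyAssembly()
    tr <- withr::with_seed(1, randomBedTrack(100, asm, maxLen = 500)$gr)
    s1 <- shuffleTrack(tr, asm, seed = 99)
    s2 <- shuffleTrack(tr, asm, seed = 99)
    s3 <- shuffleTrack(tr, asm, seed = 100)
    expect_identical(grToBed(s1), grToBed(s2))   # bit-identical given seed
    expect_false(identical(grToBed(s1), grToBed(s3)))
    expect_identical(sort(GenomicRanges::width(s1)),
                     sort(GenomicRanges::width(tr)))
    expect_identical(sort(GenomicRanges::width(s3)),
                     sort(GenomicRanges::width(tr)))
    lens <- GenomeInfoDb::seqlengths(asm)
    expect_true(all(GenomicRanges::start(s1) >= 1))
    expect_true(all(GenomicRanges::end(s1) <=
                        lens[as.character(GenomicRanges::seqnames(s1))]))

    # single valid placement: chromosome-length interval lands at 0
    one <- makeAssembly("chrA", 5000)
    placed <- shuffleTrack(makeTrack("chrA", 0, 5000, assembly = one),
                           one, seed = 3)
    expect_equal(grToBed(placed),
                 data.frame(chrom = "chrA", start = 0, end = 5000,
                            stringsAsFactors = FALSE))
    # unplaceable interval
    expect_error(shuffleTrack(makeTrack("chr1", 0, 9000), one, seed = 1),
                 "longer than every chromosome")
})

test_that("shuffle chromosome choice is uniform over equal-length chromosomes", {
    asm <- makeAssembly(c("chrA", "chrB"), c(20000, 20000))
    tr <- makeTrack("chrA", 0, 1000, assembly = asm)
    hits <- vapply(1:10000, function(i)
        as.character(GenomicRanges::seqnames(
            shuffleTrack(tr, asm, seed = i))) == "chrA", logical(1))
    # binomial test against p = 0.5, alpha = 0.001
    expect_gt(stats::binom.test(sum(hits), 10000, 0.5)$p.value, 0.001)
})
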