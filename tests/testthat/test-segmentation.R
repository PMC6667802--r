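test_that("constant signal yields a single segment", {
    cfg <- methylConfig()
    pos <- seq(1, 400, by = 10)
    seg <- segmentChromosome(rep(0.8, 40), pos, cfg)
    expect_equal(length(seg), 1L)
    expect_equal(S4Vectors::mcols(seg)$meanMeth, 0.8)
    expect_equal(S4Vectors::mcols(seg)$nCpg, 40L)
    expect_equal(GenomicRanges::start(seg), 1)
    expect_equal(GenomicRanges::end(seg), 391)
    expect_error(segmentChromosome(numeric(0), integer(0), cfg), "empty")
})

test_that("a noiseless two-level signal splits exactly at the step", {
    cfg <- methylConfig()
    x <- c(rep(0.1, 20), rep(0.9, 20))
    pos <- seq_len(40) * 10
    # independent oracle: evaluate every admissible single split
    oracle <- bruteBestSplit(x, cfg@minCpgPerSegment)
    expect_equal(oracle$split, 20L)
    seg <- segmentChromosome(x, pos, cfg)
    expect_equal(length(seg), 2L)
    expect_equal(S4Vectors::mcols(seg)$nCpg, c(20L, 20L))
    expect_equal(S4Vectors::mcols(seg)$meanMeth, c(0.1, 0.9))
})

test_that("sequences shorter than the minimum stay unsplit", {
    cfg <- methylConfig()
    x <- c(rep(0, 5), rep(1, 4))
    seg <- segmentChromosome(x, seq_len(9), cfg)
    expect_equal(length(seg), 1L)
})

test_that("segments tile the CpG sequence", {
    set.seed(12)
    cfg <- methylConfig()
    x <- c(rbeta(60, 17, 3), rbeta(40, 1, 19), rbeta(80, 17, 3))
    pos <- cumsum(1 + rgeom(180, 1 / 50))
    seg <- segmentChromosome(x, pos, cfg)
    expect_equal(sum(S4Vectors::mcols(seg)$nCpg), 180L)
    expect_true(all(GenomicRanges::start(seg)[-1] >
                    GenomicRanges::end(seg)[-length(seg)]))
    expect_false(is.unsorted(GenomicRanges::start(seg)))
})

test_that("lowering the penalty never decreases the segment count", {
    set.seed(3)
    x <- rbeta(300, 5, 5)
    pos <- seq_len(300) * 7
    counts <- vapply(c(2, 1, 0.5, 0.1, 0.02, 0.005), function(pen) {
        cfg <- methylConfig(cpPenalty = pen)
        length(segmentChromosome(x, pos, cfg))
    }, 0L)
    expect_true(all(diff(counts) >= 0))
})

test_that("piecewise-constant signals with large gaps are recovered exactly", {
    cfg <- methylConfig()
    levels <- c(0.85, 0.1, 0.55, 0.9, 0.2)
    sizes <- c(40, 25, 30, 50, 20)
    x <- rep(levels, sizes)
    pos <- seq_along(x) * 10
    seg <- segmentChromosome(x, pos, cfg)
    expect_equal(S4Vectors::mcols(seg)$nCpg, as.integer(sizes))
    expect_equal(S4Vectors::mcols(seg)$meanMeth, levels)
})

test_that("class assignment equals one point per class on spread means", {
    seg <- makeSegmentSet("chr1", c(1, 101, 201, 301),
                          c(100, 200, 300, 400),
                          meanMeth = c(0.05, 0.30, 0.60, 0.90),
                          segClass = NA)
    out <- assignClasses(seg, 4)
    expect_equal(S4Vectors::mcols(segments(out))$segClass, 1:4)
})

test_that("well-separated clusters get distinct ordered classes", {
    seg <- makeSegmentSet("chr1", seq(1, 501, by = 100),
                          seq(100, 600, by = 100),
                          meanMeth = c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),
                          segClass = NA)
    out <- assignClasses(seg, 2)
    expect_equal(S4Vectors::mcols(segments(out))$segClass,
                 c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("dynamic-programming clustering attains the exhaustive optimum", {
    set.seed(101)
    for (rep in 1:8) {
        n <- sample(10:30, 1)
        x <- runif(n)
        k <- 4
        cl <- methylStates:::kmeans1dDp(x, k)
        expect_equal(assignmentSse(x, cl), bruteKmeansSse(x, k),
                     tolerance = 1e-10)
        # class centers strictly increase with the label
        centers <- vapply(split(x, cl), mean, 0)
        expect_true(all(diff(centers) > 0))
    }
})

test_that("fewer segments than classes reduces k with a warning", {
    seg <- makeSegmentSet("chr1", c(1, 101), c(100, 200),
                          meanMeth = c(0.2, 0.8), segClass = NA)
    expect_warning(out <- assignClasses(seg, 4), "reducing k")
    expect_equal(S4Vectors::mcols(segments(out))$segClass, 1:2)
})

test_that("the segment table is sorted and bounded", {
    m <- makeMethylome(seq(1, 2000, by = 10),
                       rep(c(0.9, 0.1), each = 100), cov = 10)
    seg <- segmentMethylome(m, methylConfig(kClasses = 2))
    tab <- segmentMeanTable(seg)
    expect_equal(nrow(tab), length(segments(seg)))
    expect_false(is.unsorted(tab$start))
    expect_true(all(tab$meanMeth >= 0 & tab$meanMeth <= 1))
})
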