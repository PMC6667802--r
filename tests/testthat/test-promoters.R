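# gene models with one + strand and one - strand transcript
twoGeneModels <- function() {
    ex <- c(gr("chr1", 5001, 5200, geneId = "gP", transcriptId = "gP_t1"),
            gr("chr1", 4801, 5001, geneId = "gM", transcriptId = "gM_t1"))
    GenomicRanges::strand(ex) <- c("+", "-")
    methylStates:::GeneModels(ex)
}

test_that("promoter windows are strand-aware and clamped", {
    gm <- twoGeneModels()
    p <- extractPromoters(gm, 1000, 200)
    plus <- p[S4Vectors::mcols(p)$geneId == "gP"]
    # 0-based [4000, 5200) == 1-based 4001..5200
    expect_equal(GenomicRanges::start(plus), 4001)
    expect_equal(GenomicRanges::end(plus), 5200)
    minus <- p[S4Vectors::mcols(p)$geneId == "gM"]
    # tss at 5000 on -: 0-based [4800, 6000) == 1-based 4801..6000
    expect_equal(GenomicRanges::start(minus), 4801)
    expect_equal(GenomicRanges::end(minus), 6000)

    exNear <- gr("chr1", 301, 500, geneId = "gE", transcriptId = "gE_t1")
    GenomicRanges::strand(exNear) <- "+"
    pE <- extractPromoters(methylStates:::GeneModels(exNear), 1000, 200,
                           chromLengths = c(chr1 = 10000))
    expect_equal(GenomicRanges::start(pE), 1)  # clamped at chromosome start
    expect_equal(GenomicRanges::end(pE), 500)
})

test_that("promoter mean methylation is the unweighted CpG mean", {
    m <- makeMethylome(c(100, 150, 200), c(1, 0.5, 0), cov = c(10, 20, 40))
    out <- promoterMeanMethylation(m, gr("chr1", 50, 250))
    expect_equal(out$meanMethPct, 50)
    expect_equal(out$nCpgCovered, 3L)
    none <- promoterMeanMethylation(m, gr("chr1", 1000, 2000))
    expect_true(is.na(none$meanMethPct))
    expect_equal(none$nCpgCovered, 0L)
})

test_that("the hypermethylation rule combines class and blocking regions", {
    segs <- makeSegmentSet("chr1", c(1, 3001), c(3000, 10000),
                           meanMeth = c(0.9, 0.3), segClass = c(4, 2))
    m <- makeMethylome(seq(1100, 2200, by = 50), rep(0.9, 23), cov = 10)
    prom <- gr("chr1", 1001, 2200, geneId = "g1", transcriptId = "t1",
               tss = 2001)
    GenomicRanges::strand(prom) <- "+"
    cfg <- methylConfig()

    noReg <- makeRegionSet()
    pc <- callPromoters(prom, segs, noReg, m, cfg)
    expect_true(pc$hypermethylated)
    expect_equal(pc$locatedClass, 4L)

    # a 600 bp UMR in the promoter blocks the call
    block <- makeRegionSet("chr1", 1500, 2099, "UMR")
    expect_false(callPromoters(prom, segs, block, m,
                               cfg)$hypermethylated)
    # a 400 bp LMR is below the size filter and does not block
    small <- makeRegionSet("chr1", 1500, 1899, "LMR")
    expect_true(callPromoters(prom, segs, small, m, cfg)$hypermethylated)

    # majority segment of class 2 fails regardless of regions
    prom2 <- gr("chr1", 2901, 4100, geneId = "g2", transcriptId = "t2",
                tss = 3901)
    GenomicRanges::strand(prom2) <- "+"
    expect_false(callPromoters(prom2, segs, noReg, m,
                               cfg)$hypermethylated)
})

test_that("promoters demand a segment cover on their chromosome", {
    elsewhere <- makeSegmentSet("chr2", 1, 1000, meanMeth = 0.5,
                                segClass = 1)
    prom <- gr("chr1", 100, 300, geneId = "g", transcriptId = "t",
               tss = 100)
    m <- makeMethylome(c(150, 250), c(0.5, 0.5))
    expect_error(
        callPromoters(prom, elsewhere, makeRegionSet(), m,
                      methylConfig()),
        "no segments on chromosome")
})

test_that("adding a large blocking region never rescues a promoter", {
    set.seed(33)
    segs <- makeSegmentSet("chr1", c(1, 5001), c(5000, 9000),
                           meanMeth = c(0.85, 0.1), segClass = c(4, 1))
    m <- makeMethylome(seq(100, 8900, by = 100), rep(0.8, 89), cov = 10)
    cfg <- methylConfig()
    for (i in 1:10) {
        st <- sample(1:8000, 1)
        prom <- gr("chr1", st, st + 1199, geneId = "g",
                   transcriptId = "t", tss = st)
        GenomicRanges::strand(prom) <- "+"
        before <- callPromoters(prom, segs, makeRegionSet(), m,
                                cfg)$hypermethylated
        withReg <- callPromoters(
            prom, segs, makeRegionSet("chr1", st, st + 600, "UMR"), m,
            cfg)$hypermethylated
        expect_true(withReg <= before)   # monotone: can only turn off
    }
})

test_that("representative selection takes the lowest qualifying mean", {
    pc <- data.frame(
        geneId = c("g1", "g1", "g2"),
        transcriptId = c("t1", "t2", "t3"),
        chrom = "chr1", start = c(1000, 3000, 6000),
        end = c(2199, 4199, 7199), strand = "+",
        tss = c(2000, 4000, 7000),
        meanMethPct = c(85, 12, 90), nCpgCovered = 30L,
        locatedClass = c(4L, 1L, 4L),
        locatedSegWidth = c(5000, 2000, 5000),
        nBlockingRegions = c(0L, 1L, 0L),
        maxOverlapRegionWidth = c(0, 1500, 0),
        hypermethylated = c(TRUE, FALSE, TRUE))
    gc <- selectRepresentative(pc)
    g1 <- gc[gc$geneId == "g1", ]
    expect_equal(g1$representativeMeanMethPct, 12)
    expect_false(g1$geneHypermethylated)   # not all promoters hyper
    g2 <- gc[gc$geneId == "g2", ]
    expect_equal(g2$representativeTranscript, "t3")
    expect_true(g2$geneHypermethylated)
    expect_error(selectRepresentative(pc[0, ]), "no promoter calls")
})

test_that("mean ties resolve to the 5'-most TSS", {
    base <- data.frame(
        geneId = "g", transcriptId = c("a", "b"), chrom = "chr1",
        start = c(1000, 3000), end = c(2199, 4199), strand = "+",
        tss = c(2000, 4000), meanMethPct = c(40, 40), nCpgCovered = 10L,
        locatedClass = 4L, locatedSegWidth = 6000,
        nBlockingRegions = 0L, maxOverlapRegionWidth = 0,
        hypermethylated = TRUE)
    expect_equal(selectRepresentative(base)$representativeTranscript, "a")
    minus <- base; minus$strand <- "-"
    expect_equal(selectRepresentative(minus)$representativeTranscript, "b")
})

test_that("gene-set percentages count hypermethylated genes", {
    gc <- data.frame(geneId = paste0("g", 1:10),
                     representativeTranscript = "t",
                     representativeMeanMethPct = 50, nPromoters = 1L,
                     geneHypermethylated = c(rep(TRUE, 5), rep(FALSE, 5)))
    expect_equal(geneSetPercentage(gc, paste0("g", 1:10)), 50)
    expect_equal(geneSetPercentage(gc, paste0("g", 6:10)), 0)
    expect_equal(geneSetPercentage(gc, c("g1", "g2", "g3", "g4", "g6",
                                         "g7", "g8", "g9")), 50)
    expect_warning(p <- geneSetPercentage(gc, c("g1", "gX")), "absent")
    expect_equal(p, 100)
    expect_error(geneSetPercentage(gc, c("gX", "gY")), "no gene")
})

test_that("heatmap matrices keep gene rows and sample columns aligned", {
    gcA <- data.frame(geneId = c("g1", "g2"),
                      representativeTranscript = "t",
                      representativeMeanMethPct = c(85, NA),
                      nPromoters = 1L, geneHypermethylated = TRUE)
    gcB <- data.frame(geneId = c("g2", "g1"),
                      representativeTranscript = "t",
                      representativeMeanMethPct = c(10, 20),
                      nPromoters = 1L, geneHypermethylated = FALSE)
    hm <- buildHeatmapMatrix(list(sampleA = gcA, sampleB = gcB),
                             c("g1", "g2", "g3"))
    expect_equal(dim(hm), c(3L, 2L))
    expect_equal(colnames(hm), c("sampleA", "sampleB"))
    expect_equal(hm["g1", ], c(sampleA = 85, sampleB = 20))
    expect_true(is.na(hm["g2", "sampleA"]))
    expect_true(all(is.na(hm["g3", ])))
    one <- buildHeatmapMatrix(list(s = gcA), "g1")
    expect_equal(dim(one), c(1L, 1L))
})

test_that("CpG profiles orient offsets by strand and union intervals", {
    m <- makeMethylome(c(5000, 5100, 5150), c(0.8, 0.4, 0.2), cov = 10)
    promPlus <- gr("chr1", 4001, 5200, tss = 5000)
    GenomicRanges::strand(promPlus) <- "+"
    firstExon <- gr("chr1", 5000, 5199)   # overlaps the promoter window
    out <- cpgProfile(m, promPlus, firstExon)
    expect_equal(out$profile$offset, c(0, 100, 150))
    expect_equal(nrow(out$profile), 3L)   # overlap CpGs counted once
    expect_equal(out$meanPct, mean(c(80, 40, 20)))

    promMinus <- gr("chr1", 4901, 6100, tss = 5000)
    GenomicRanges::strand(promMinus) <- "-"
    outM <- cpgProfile(m, promMinus, gr("chr1", 4901, 5000))
    expect_equal(outM$profile$offset, c(-150, -100, 0))
})
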