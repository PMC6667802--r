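smallDesign <- function(...) {
    simDesign(chromLengths = c(chr1 = 3e5), nPhotoreceptorGenes = 3,
              otherSets = c(rgc = 4), nExtraUmr = 2, nExtraLmr = 4, ...)
}

test_that("layout generation is deterministic under a fixed seed", {
    des <- smallDesign()
    l1 <- simulateLayout(des, 5)
    l2 <- simulateLayout(des, 5)
    expect_identical(GenomicRanges::start(l1$cpgSites),
                     GenomicRanges::start(l2$cpgSites))
    expect_identical(l1$slots, l2$slots)
    expect_identical(exons(l1$geneModels), exons(l2$geneModels))
})

test_that("island CpG spacing matches the design within 20%", {
    des <- simDesign(chromLengths = c(chr1 = 2e6), nPhotoreceptorGenes = 0,
                     otherSets = integer(0), nExtraUmr = 40, nExtraLmr = 0,
                     umrLenRange = c(3000, 5000), islandSpacing = 10)
    l <- simulateLayout(des, 3)
    isl <- l$slots[S4Vectors::mcols(l$slots)$slotType == "umr"]
    inIsl <- IRanges::overlapsAny(l$cpgSites, isl)
    sp <- unlist(lapply(seq_along(isl), function(i) {
        p <- GenomicRanges::start(l$cpgSites[IRanges::overlapsAny(
            l$cpgSites, isl[i])])
        diff(p)
    }))
    expect_gt(length(sp), 1000)
    expect_lt(abs(mean(sp) - 10) / 10, 0.2)
    # background spacing likewise near its design value
    bg <- diff(GenomicRanges::start(l$cpgSites[!inIsl]))
    expect_lt(abs(mean(bg[bg < 2000]) - 100) / 100, 0.25)
})

test_that("a layout with zero genes still has a valid CpG landscape", {
    des <- simDesign(chromLengths = c(chr1 = 1e5), nPhotoreceptorGenes = 0,
                     otherSets = integer(0), nExtraUmr = 1, nExtraLmr = 1)
    l <- simulateLayout(des, 1)
    expect_equal(length(exons(l$geneModels)), 0L)
    expect_gt(length(l$cpgSites), 500)
    expect_false(is.unsorted(GenomicRanges::start(l$cpgSites)))
})

test_that("a chromosome too short for the requested slots errors", {
    des <- simDesign(chromLengths = c(chr1 = 2e4), nPhotoreceptorGenes = 5,
                     otherSets = c(x = 5))
    expect_error(simulateLayout(des, 1), "too short")
})

test_that("planted states follow the two-condition promoter map", {
    des <- smallDesign()
    l <- simulateLayout(des, 5)
    prom <- extractPromoters(l$geneModels, chromLengths = des@chromLengths)
    photo <- S4Vectors::mcols(prom)$geneId %in% l$geneSets$photoreceptor

    trRpc <- plantStates(l, des, "RPC-like", 6)
    regs <- truthRegions(trRpc)
    hit <- GenomicRanges::findOverlaps(prom, regs, select = "arbitrary")
    stateOf <- S4Vectors::mcols(regs)$trueState[hit]
    expect_true(all(S4Vectors::mcols(regs)$trueMean[hit][photo] >= 0.8))
    expect_true(all(stateOf[!photo] == "UMR"))

    trRod <- plantStates(l, des, "rod-like", 6)
    regs2 <- truthRegions(trRod)
    hit2 <- GenomicRanges::findOverlaps(prom, regs2, select = "arbitrary")
    expect_true(all(S4Vectors::mcols(regs2)$trueMean[hit2][photo] <= 0.3))
    expect_true(all(S4Vectors::mcols(regs2)$trueState[hit2][!photo] ==
                    "UMR"))

    ic <- intendedCalls(trRpc)
    expect_true(all(ic$hypermethylated[ic$geneId %in%
                                       l$geneSets$photoreceptor]))
    expect_false(any(intendedCalls(trRod)$hypermethylated))
})

test_that("planted regions tile each chromosome without gaps", {
    des <- smallDesign()
    l <- simulateLayout(des, 2)
    tr <- plantStates(l, des, "RPC-like", 2)
    g <- GenomicRanges::sort(truthRegions(tr), ignore.strand = TRUE)
    expect_equal(GenomicRanges::start(g)[1], 1)
    expect_equal(GenomicRanges::end(g)[length(g)],
                 unname(des@chromLengths[["chr1"]]))
    expect_true(all(GenomicRanges::start(g)[-1] ==
                    GenomicRanges::end(g)[-length(g)] + 1))
})

test_that("FMR-only probabilities concentrate near the Beta mean", {
    des <- simDesign(chromLengths = c(chr1 = 1.2e6),
                     nPhotoreceptorGenes = 0, otherSets = integer(0),
                     nExtraUmr = 0, nExtraLmr = 0)
    l <- simulateLayout(des, 4)
    tr <- plantStates(l, des, "RPC-like", 4)
    p <- S4Vectors::mcols(truthSiteProbs(tr))$p
    expect_gt(length(p), 1e4)
    expect_true(mean(p) >= 0.80 && mean(p) <= 0.90)
})

test_that("simulated counts have the designed coverage and edge cases", {
    des <- simDesign(chromLengths = c(chr1 = 1.2e6),
                     nPhotoreceptorGenes = 0, otherSets = integer(0),
                     nExtraUmr = 0, nExtraLmr = 0, rho = 0,
                     coverageLambda = 20)
    l <- simulateLayout(des, 8)
    tr <- plantStates(l, des, "RPC-like", 8)
    m <- simulateCounts(tr, des, 8)
    cov <- S4Vectors::mcols(methSites(m))$countTotal
    expect_gt(length(cov), 1e4)
    # mean of Poisson(20) conditional on >0 is essentially 20
    expect_true(mean(cov) >= 19 && mean(cov) <= 21)

    # degenerate probabilities propagate exactly
    tr2 <- tr
    S4Vectors::mcols(tr2@siteProbs)$p <- 1
    m1 <- simulateCounts(tr2, des, 9)
    expect_true(all(methFraction(m1) == 1))
    S4Vectors::mcols(tr2@siteProbs)$p <- 0
    m0 <- simulateCounts(tr2, des, 9)
    expect_true(all(methFraction(m0) == 0))
})

test_that("observed region means converge to the planted truth", {
    des <- smallDesign(rho = 0.05)
    ex <- simulateExperiment(des, 21)
    m <- ex$samples[["rod-like"]]
    regs <- truthRegions(ex$truth[["rod-like"]])
    s <- methSites(m); fr <- methFraction(m)
    hit <- GenomicRanges::findOverlaps(regs, s)
    for (i in unique(S4Vectors::queryHits(hit))) {
        idx <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]
        if (length(idx) >= 50)
            expect_lt(abs(mean(fr[idx]) -
                          S4Vectors::mcols(regs)$trueMean[i]), 0.05)
    }
})

test_that("a simulated experiment is deterministic and io-stable", {
    des <- smallDesign()
    e1 <- simulateExperiment(des, 13)
    e2 <- simulateExperiment(des, 13)
    expect_identical(methSites(e1$samples[["RPC-like"]]),
                     methSites(e2$samples[["RPC-like"]]))
    expect_identical(e1$truth[["rod-like"]]@regions,
                     e2$truth[["rod-like"]]@regions)
    f <- tempfile()
    writeCytosineReport(e1$samples[["rod-like"]], f)
    back <- readCytosineReport(f, minCov = 1, sampleId = "rod-like")
    expect_identical(methSites(back), methSites(e1$samples[["rod-like"]]))
})
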