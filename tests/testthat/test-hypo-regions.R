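test_that("running-mean smoothing matches hand arithmetic", {
    expect_equal(smoothFractions(rep(0.5, 10), 3), rep(0.5, 10))
    expect_equal(smoothFractions(c(0, 1, 0), 3), c(0.5, 1 / 3, 0.5))
    x <- runif(20)
    expect_identical(smoothFractions(x, 1), x)
    expect_error(smoothFractions(x, 4))
})

test_that("candidate regions are maximal qualifying low runs", {
    sm <- rep(0.9, 30)
    expect_equal(length(candidateRegions(sm, sm, seq_len(30) * 10,
                                         0.5, 4)), 0L)
    fr <- c(rep(0.9, 10), rep(0.1, 10), rep(0.9, 10))
    pos <- seq_len(30) * 10
    reg <- candidateRegions(fr, fr, pos, 0.5, 4)
    expect_equal(length(reg), 1L)
    expect_equal(S4Vectors::mcols(reg)$nCpg, 10L)
    expect_equal(S4Vectors::mcols(reg)$meanMeth, 0.1)
    expect_equal(GenomicRanges::start(reg), 110)
    expect_equal(GenomicRanges::end(reg), 200)
    # run shorter than n_min is dropped
    fr2 <- c(rep(0.9, 10), rep(0.1, 3), rep(0.9, 10))
    expect_equal(length(candidateRegions(fr2, fr2, seq_len(23) * 10,
                                         0.5, 4)), 0L)
})

test_that("calibration selects cutoffs recovering planted UMRs", {
    # 50 planted 10-CpG UMRs at 0.05 inside a 0.9 background
    set.seed(1)
    fr <- rep(0.9, 10500)
    starts <- seq(100, by = 200, length.out = 50)
    for (s in starts) fr[s:(s + 9)] <- 0.05
    pos <- seq_along(fr) * 10
    m <- makeMethylome(pos, fr, cov = 20)
    cfg <- methylConfig(nPerm = 10)
    res <- calibrateFdr(m, cfg, seed = 1)
    sel <- res@grid[res@grid$m == res@mStar & res@grid$n == res@nStar, ]
    expect_gte(sel$observed, 50)
    expect_lte(sel$fdr, 0.05)
    regs <- callUmrLmr(m, res, cfg)
    expect_gte(length(regions(regs)), 50)
})

test_that("pure-noise methylomes defeat cutoff selection", {
    set.seed(4)
    fr <- runif(5000)
    m <- makeMethylome(seq_len(5000) * 20, round(fr * 20) / 20, cov = 20)
    expect_error(calibrateFdr(m, methylConfig(nPerm = 10), seed = 2),
                 "no \\(m, n\\) grid pair")
})

test_that("calibration requires at least one permutation", {
    m <- makeMethylome(1:50 * 10, rep(0.5, 50), cov = 10)
    expect_error(calibrateFdr(m, methylConfig(nPerm = 0)), "nPerm >= 1")
})

test_that("UMR/LMR typing splits at the CpG-count threshold", {
    fr <- c(rep(0.9, 20), rep(0.05, 35), rep(0.9, 20), rep(0.05, 5),
            rep(0.9, 20))
    pos <- seq_along(fr) * 10
    m <- makeMethylome(pos, fr, cov = 20)
    res <- new("FdrGridResult", grid = data.frame(), mStar = 0.5,
               nStar = 4L, fdrTarget = 0.05)
    regs <- regions(callUmrLmr(m, res, methylConfig()))
    expect_equal(length(regs), 2L)
    ty <- S4Vectors::mcols(regs)$regionType
    nc <- S4Vectors::mcols(regs)$nCpg
    expect_equal(ty[nc >= 30], "UMR")
    expect_equal(ty[nc < 30], "LMR")
    expect_equal(S4Vectors::mcols(regs)$sizeBp,
                 GenomicRanges::width(regs))
})

test_that("called regions are disjoint, sorted and below background", {
    set.seed(7)
    fr <- pmin(1, pmax(0, rnorm(4000, 0.85, 0.07)))
    starts <- seq(200, by = 400, length.out = 8)
    for (s in starts) fr[s:(s + 14)] <- pmax(0, rnorm(15, 0.05, 0.03))
    m <- makeMethylome(seq_along(fr) * 10, round(fr * 20) / 20, cov = 20)
    cfg <- methylConfig(nPerm = 5)
    res <- calibrateFdr(m, cfg, seed = 3)
    g <- regions(callUmrLmr(m, res, cfg))
    expect_gt(length(g), 0)
    expect_false(is.unsorted(GenomicRanges::start(g)))
    if (length(g) > 1)
        expect_true(all(GenomicRanges::start(g)[-1] >
                        GenomicRanges::end(g)[-length(g)]))
    expect_true(all(S4Vectors::mcols(g)$meanMeth < mean(methFraction(m))))
})

test_that("null methylomes yield almost no calls at selected cutoffs", {
    set.seed(5)
    fr <- pmin(1, pmax(0, rnorm(6000, 0.85, 0.07)))
    starts <- seq(150, by = 300, length.out = 15)
    for (s in starts) fr[s:(s + 14)] <- 0.05
    m <- makeMethylome(seq_along(fr) * 10, round(fr * 20) / 20, cov = 20)
    cfg <- methylConfig(nPerm = 5)
    res <- calibrateFdr(m, cfg, seed = 4)
    observed <- length(regions(callUmrLmr(m, res, cfg)))
    nullCounts <- vapply(1:20, function(s)
        methylStates:::nullRegionCount(m, res@mStar, res@nStar,
                                       window = 3, seed = s), 0L)
    expect_lte(mean(nullCounts), 0.05 * observed)
})
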