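# in-code fixture builders and independent oracles shared across tests

gr <- function(chrom, start, end, ...) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

# Methylome from fractions at given coverage (fraction * cov must be whole)
makeMethylome <- function(pos, fraction, cov = 10L, chrom = "chr1",
                          sampleId = "test") {
    cov <- rep_len(as.integer(cov), length(pos))
    meth <- as.integer(round(fraction * cov))
    g <- gr(chrom, pos, pos, countMeth = meth, countTotal = cov)
    Methylome(sampleId, g)
}

makeSegmentSet <- function(chrom, start, end, meanMeth, segClass,
                           nCpg = 10L) {
    g <- gr(chrom, start, end, nCpg = rep_len(as.integer(nCpg),
                                              length(start)),
            meanMeth = meanMeth, segClass = as.integer(segClass))
    methylStates:::SegmentSet(GenomicRanges::sort(g, ignore.strand = TRUE))
}

makeRegionSet <- function(chrom = character(0), start = integer(0),
                          end = integer(0), regionType = character(0),
                          meanMeth = NULL, nCpg = NULL) {
    if (is.null(meanMeth)) meanMeth <- rep(0.05, length(start))
    if (is.null(nCpg)) nCpg <- rep(20L, length(start))
    g <- gr(chrom, start, end, nCpg = as.integer(nCpg),
            meanMeth = meanMeth, regionType = regionType,
            sizeBp = end - start + 1L)
    methylStates:::RegionSet(GenomicRanges::sort(g, ignore.strand = TRUE))
}

# brute-force single best SSE split of a fraction vector
bruteBestSplit <- function(x, minC) {
    n <- length(x)
    sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
    s <- seq.int(minC, n - minC)
    gain <- vapply(s, function(k)
        sse(x) - sse(x[1:k]) - sse(x[(k + 1):n]), 0)
    list(split = s[which.max(gain)], gain = max(gain))
}

# exhaustive optimal 1-D k-clustering SSE over all ordered cut placements
bruteKmeansSse <- function(x, k) {
    xs <- sort(x)
    n <- length(xs)
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    grpSse <- function(i, j) {
        s <- cs[j] - c(0, cs)[i]
        s2 <- cs2[j] - c(0, cs2)[i]
        s2 - s^2 / (j - i + 1)
    }
    if (k == 1) return(grpSse(1L, n))
    cuts <- utils::combn(n - 1L, k - 1L)
    best <- Inf
    for (c in seq_len(ncol(cuts))) {
        b <- c(0L, cuts[, c], n)
        tot <- sum(grpSse(b[-length(b)] + 1L, b[-1]))
        if (tot < best) best <- tot
    }
    best
}

# k-clustering SSE realized by a given assignment
assignmentSse <- function(x, cl) {
    sum(vapply(split(x, cl), function(v) sum((v - mean(v))^2), 0))
}

# exhaustive joint-path decoder for the 2-state HMM (log space)
enumerateBestPath <- function(fractions, params) {
    x <- pmin(1 - 1e-3, pmax(1e-3, fractions))
    n <- length(x)
    le <- cbind(dbeta(x, params@shape1[1], params@shape2[1], log = TRUE),
                dbeta(x, params@shape1[2], params@shape2[2], log = TRUE))
    lA <- log(params@transMat)
    lpi <- log(params@initProb)
    paths <- as.matrix(expand.grid(rep(list(1:2), n)))[, n:1, drop = FALSE]
    lp <- apply(paths, 1, function(s) {
        v <- lpi[s[1]] + le[1, s[1]]
        if (n > 1) for (t in 2:n)
            v <- v + lA[s[t - 1], s[t]] + le[t, s[t]]
        v
    })
    paths[which.max(lp), ]
}

# base-level Jaccard between two GRanges
baseJaccard <- function(a, b) {
    a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
    b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
    inter <- sum(IRanges::width(GenomicRanges::intersect(a, b,
                                                         ignore.strand = TRUE)))
    un <- sum(IRanges::width(GenomicRanges::union(a, b,
                                                  ignore.strand = TRUE)))
    inter / un
}

# random two-state HMM parameterization with separated emissions
randomHmmParams <- function() {
    p <- runif(1, 0.2, 0.8)
    a <- runif(1, 0.6, 0.99); b <- runif(1, 0.6, 0.99)
    mu <- sort(runif(2, 0.1, 0.9), decreasing = TRUE)
    conc <- runif(2, 2, 40)
    hmmParams(initProb = c(p, 1 - p),
              transMat = matrix(c(a, 1 - a, 1 - b, b), 2, byrow = TRUE),
              shape1 = mu * conc, shape2 = (1 - mu) * conc)
}

# simulate a state path + Beta emissions from HmmParams
simulateHmm <- function(n, params) {
    s <- integer(n)
    s[1] <- sample(1:2, 1, prob = params@initProb)
    if (n > 1) for (t in 2:n)
        s[t] <- sample(1:2, 1, prob = params@transMat[s[t - 1], ])
    x <- rbeta(n, params@shape1[s], params@shape2[s])
    list(states = s, fractions = x)
}
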