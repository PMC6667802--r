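#' Change-point segmentation of one chromosome's CpG fractions
#'
#' Recursive (greedy) binary segmentation of the ordered per-CpG
#' methylation fractions. At each step the candidate split maximizes the
#' decrease in within-segment sum of squared errors; a split is accepted
#' when that decrease exceeds \code{cpPenalty * log(nTotal)} (a BIC-style
#' penalty, \code{nTotal} the chromosome's CpG count) and both children
#' retain at least \code{minCpgPerSegment} CpGs. Ties in the argmax go to
#' the smallest index. The resulting segments tile the CpG sequence; each
#' segment's interval spans first to last member CpG.
#'
#' @param fractions numeric vector of methylation fractions in CpG order.
#' @param positions integer vector of 1-based CpG positions (same length).
#' @param cfg a \linkS4class{MethylConfig}.
#' @param chrom chromosome name for the output intervals.
#' @return GRanges of segments with \code{nCpg}, \code{meanMeth} and
#'   \code{segClass} (NA; assign with \code{\link{assignClasses}}).
#' @export
segmentChromosome <- function(fractions, positions, cfg, chrom = "chr1") {
    n <- length(fractions)
    if (n == 0L) stop("cannot segment an empty CpG sequence")
    stopifnot(length(positions) == n, !is.unsorted(positions))
    minC <- cfg@minCpgPerSegment
    threshold <- cfg@cpPenalty * log(n)
    csum <- cumsum(fractions)
    csum2 <- cumsum(fractions^2)
    rsum <- function(l, r) csum[r] - if (l > 1) csum[l - 1] else 0
    rsum2 <- function(l, r) csum2[r] - if (l > 1) csum2[l - 1] else 0
    sse <- function(l, r) rsum2(l, r) - rsum(l, r)^2 / (r - l + 1)

    bounds <- integer(0)        # accepted split points (last index of left)
    stack <- list(c(1L, n))
    while (length(stack)) {
        node <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        l <- node[1]; r <- node[2]
        if (r - l + 1L < 2L * minC) next
        s <- seq.int(l + minC - 1L, r - minC)   # split after index s
        nl <- s - l + 1L; nr <- r - s
        sl <- csum[s] - if (l > 1) csum[l - 1] else 0
        sl2 <- csum2[s] - if (l > 1) csum2[l - 1] else 0
        tot <- rsum(l, r); tot2 <- rsum2(l, r)
        sseL <- sl2 - sl^2 / nl
        sseR <- (tot2 - sl2) - (tot - sl)^2 / nr
        gain <- (tot2 - tot^2 / (r - l + 1L)) - sseL - sseR
        best <- which.max(gain)
        if (gain[best] > threshold) {
            sp <- s[best]
            bounds <- c(bounds, sp)
            stack[[length(stack) + 1L]] <- c(l, sp)
            stack[[length(stack) + 1L]] <- c(sp + 1L, r)
        }
    }
    bounds <- sort(bounds)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    GRanges(chrom, IRanges(positions[starts], positions[ends]),
            nCpg = ends - starts + 1L,
            meanMeth = vapply(seq_along(starts), function(i)
                rsum(starts[i], ends[i]) / (ends[i] - starts[i] + 1L), 0),
            segClass = NA_integer_)
}

#' Segment every chromosome of a methylome
#'
#' Runs \code{\link{segmentChromosome}} per chromosome and assigns ordered
#' segmentation classes across all chromosomes with
#' \code{\link{assignClasses}}.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param cfg a \linkS4class{MethylConfig}.
#' @return A \linkS4class{SegmentSet} with classes assigned.
#' @export
segmentMethylome <- function(methylome, cfg = methylConfig()) {
    byChrom <- perChromosome(methylome)
    segs <- lapply(names(byChrom), function(ch)
        segmentChromosome(byChrom[[ch]]$fraction, byChrom[[ch]]$pos, cfg,
                          chrom = ch))
    g <- GenomicRanges::sort(do.call(c, unname(segs)),
                             ignore.strand = TRUE)
    assignClasses(SegmentSet(g), cfg@kClasses)
}

# exact 1-D k-means by dynamic programming on sorted values; returns the
# globally optimal cluster id (1..k ascending by center) per input value
kmeans1dDp <- function(x, k) {
    n <- length(x)
    ord <- order(x)
    xs <- x[ord]
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    segSse <- function(i, j) {  # vectorized over i
        s <- cs[j] - c(0, cs)[i]
        s2 <- cs2[j] - c(0, cs2)[i]
        s2 - s^2 / (j - i + 1)
    }
    D <- matrix(Inf, k, n)
    B <- matrix(0L, k, n)
    D[1, ] <- segSse(rep(1L, n), seq_len(n))
    B[1, ] <- 1L
    if (k > 1) for (kk in 2:k) {
        for (j in kk:n) {
            i <- kk:j   # cluster kk covers xs[i..j]
            cost <- D[kk - 1, i - 1] + segSse(i, j)
            b <- which.min(cost)
            D[kk, j] <- cost[b]
            B[kk, j] <- i[b]
        }
    }
    cl <- integer(n)
    j <- n
    for (kk in k:1) {
        i <- B[kk, j]
        cl[i:j] <- kk
        j <- i - 1L
    }
    out <- integer(n)
    out[ord] <- cl
    out
}

#' Assign ordered segmentation classes
#'
#' Clusters segment mean methylation values into \code{k} groups with exact
#' dynamic-programming one-dimensional k-means (the global optimum of the
#' within-group sum of squares) and labels groups 1..k in ascending order
#' of group center, so class k holds the most methylated segments.
#'
#' @param segmentSet a \linkS4class{SegmentSet} (classes may be NA).
#' @param k number of classes (default 4; reduced with a warning when there
#'   are fewer segments than classes).
#' @return The \linkS4class{SegmentSet} with \code{segClass} filled in.
#' @export
assignClasses <- function(segmentSet, k = 4) {
    g <- segments(segmentSet)
    if (!length(g)) return(segmentSet)
    k <- as.integer(k)
    if (length(g) < k) {
        warning("fewer segments (", length(g), ") than classes (", k,
                "); reducing k")
        k <- length(g)
    }
    cl <- kmeans1dDp(mcols(g)$meanMeth, k)
    mcols(g)$segClass <- cl
    SegmentSet(g)
}

#' Tabulate a segmentation
#'
#' @param segmentSet a \linkS4class{SegmentSet}.
#' @return data.frame sorted by chromosome and start with columns
#'   \code{chrom}, \code{start}, \code{end} (1-based closed), \code{nCpg},
#'   \code{meanMeth}, \code{segClass}.
#' @export
segmentMeanTable <- function(segmentSet) {
    g <- segments(segmentSet)
    d <- data.frame(chrom = as.character(seqnames(g)), start = start(g),
                    end = end(g), nCpg = mcols(g)$nCpg,
                    meanMeth = mcols(g)$meanMeth,
                    segClass = mcols(g)$segClass)
    d[order(d$chrom, d$start), , drop = FALSE]
}
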