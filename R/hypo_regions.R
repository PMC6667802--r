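#' Running-mean smoothing of CpG fractions
#'
#' Centered running mean over \code{window} consecutive CpGs; at the edges
#' the window shrinks to the available neighbours. \code{window = 1} returns
#' the input unchanged.
#'
#' @param fractions numeric vector in CpG order.
#' @param window odd positive integer (default 3).
#' @return Numeric vector of smoothed fractions.
#' @export
smoothFractions <- function(fractions, window = 3) {
    window <- as.integer(window)
    stopifnot(window >= 1L, window %% 2L == 1L)
    n <- length(fractions)
    if (window == 1L || n <= 1L) return(fractions)
    h <- (window - 1L) %/% 2L
    cs <- c(0, cumsum(fractions))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# run-length machinery shared by candidate calling and the FDR grid:
# maximal runs of smoothed fraction < m, as (startIdx, endIdx) pairs
lowRuns <- function(smoothed, m) {
    r <- rle(smoothed < m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
}

#' Candidate hypomethylated regions at fixed cutoffs
#'
#' Maximal runs of consecutive CpGs whose smoothed fraction falls below
#' \code{m}, kept when the run spans at least \code{nMin} CpGs. The region
#' interval spans first to last member CpG; its mean methylation is the
#' mean of the raw (unsmoothed) fractions in the run.
#'
#' @param smoothed smoothed fractions (see \code{\link{smoothFractions}}).
#' @param fractions raw fractions, same order.
#' @param positions 1-based CpG positions.
#' @param m methylation cutoff.
#' @param nMin minimum CpGs per region.
#' @param chrom chromosome name.
#' @return GRanges with \code{nCpg} and \code{meanMeth}.
#' @export
candidateRegions <- function(smoothed, fractions, positions, m, nMin,
                             chrom = "chr1") {
    runs <- lowRuns(smoothed, m)
    len <- runs[, "end"] - runs[, "start"] + 1L
    runs <- runs[len >= nMin, , drop = FALSE]
    if (!nrow(runs))
        return(GRanges(nCpg = integer(0), meanMeth = numeric(0)))
    GRanges(chrom, IRanges(unname(positions[runs[, "start"]]),
                           unname(positions[runs[, "end"]])),
            nCpg = unname(runs[, "end"] - runs[, "start"] + 1L),
            meanMeth = vapply(seq_len(nrow(runs)), function(i)
                mean(fractions[runs[i, "start"]:runs[i, "end"]]), 0))
}

# counts of runs >= n for every n in nGrid, given run lengths
countRunsGE <- function(runLens, nGrid) {
    if (!length(runLens)) return(integer(length(nGrid)))
    vapply(nGrid, function(n) sum(runLens >= n), 0L)
}

#' Calibrate UMR/LMR detection cutoffs by permutation FDR
#'
#' For every grid pair (methylation cutoff \code{m}, minimum run length
#' \code{n}) the observed region count is compared with the mean count on
#' randomized methylomes in which the fractions are shuffled across CpG
#' positions within each chromosome (positions, and the counts attached to
#' each fraction, stay fixed). The FDR estimate is randomized/observed
#' (0/0 counts as 0, capped at 1). Among pairs meeting
#' \code{cfg@fdrTarget}, the pair maximizing the observed count is
#' selected; ties resolve to the smaller \code{m}, then smaller \code{n}.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param cfg a \linkS4class{MethylConfig} (grid, window, target, nPerm).
#' @param seed integer seed for the permutations.
#' @return An \linkS4class{FdrGridResult}.
#' @export
calibrateFdr <- function(methylome, cfg = methylConfig(), seed = 1) {
    if (cfg@nPerm < 1L)
        stop("calibrateFdr needs nPerm >= 1 permutation")
    set.seed(as.integer(seed))
    byChrom <- perChromosome(methylome)
    mGrid <- cfg@mGrid; nGrid <- cfg@nGrid
    obs <- matrix(0L, length(mGrid), length(nGrid))
    rnd <- matrix(0, length(mGrid), length(nGrid))
    for (ch in names(byChrom)) {
        fr <- byChrom[[ch]]$fraction
        sm <- smoothFractions(fr, cfg@smoothWindow)
        for (a in seq_along(mGrid)) {
            runs <- lowRuns(sm, mGrid[a])
            obs[a, ] <- obs[a, ] +
                countRunsGE(runs[, "end"] - runs[, "start"] + 1L, nGrid)
        }
        for (p in seq_len(cfg@nPerm)) {
            smP <- smoothFractions(sample(fr), cfg@smoothWindow)
            for (a in seq_along(mGrid)) {
                runs <- lowRuns(smP, mGrid[a])
                rnd[a, ] <- rnd[a, ] +
                    countRunsGE(runs[, "end"] - runs[, "start"] + 1L,
                                nGrid)
            }
        }
    }
    rnd <- rnd / cfg@nPerm
    fdr <- ifelse(obs == 0 & rnd == 0, 0, pmin(1, rnd / pmax(obs, 1e-12)))
    grid <- data.frame(m = rep(mGrid, times = length(nGrid)),
                       n = rep(nGrid, each = length(mGrid)),
                       observed = as.vector(obs),
                       randomizedMean = as.vector(rnd),
                       fdr = as.vector(fdr))
    ok <- grid$fdr <= cfg@fdrTarget & grid$observed > 0
    if (!any(ok))
        stop("no (m, n) grid pair reaches FDR <= ", cfg@fdrTarget,
             "; consider longer minimum runs (larger n) or stricter ",
             "cutoffs (smaller m)")
    cand <- grid[ok, , drop = FALSE]
    cand <- cand[order(-cand$observed, cand$m, cand$n), , drop = FALSE]
    new("FdrGridResult", grid = grid, mStar = cand$m[1],
        nStar = as.integer(cand$n[1]), fdrTarget = cfg@fdrTarget)
}

#' Call UMRs and LMRs at calibrated cutoffs
#'
#' Candidate regions at the selected (m*, n*) become unmethylated regions
#' (UMR) when they contain at least \code{cfg@umrLmrCpgThreshold} CpGs and
#' low-methylated regions (LMR) otherwise. No size filtering happens here;
#' the >500 bp rule applies at promoter-classification time.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param fdrResult an \linkS4class{FdrGridResult}.
#' @param cfg a \linkS4class{MethylConfig}.
#' @return A \linkS4class{RegionSet} of UMRs and LMRs.
#' @export
callUmrLmr <- function(methylome, fdrResult, cfg = methylConfig()) {
    byChrom <- perChromosome(methylome)
    m <- fdrResult@mStar; nMin <- fdrResult@nStar
    out <- lapply(names(byChrom), function(ch) {
        fr <- byChrom[[ch]]$fraction
        sm <- smoothFractions(fr, cfg@smoothWindow)
        candidateRegions(sm, fr, byChrom[[ch]]$pos, m, nMin, chrom = ch)
    })
    g <- do.call(c, unname(out))
    if (length(g)) {
        g <- GenomicRanges::sort(g, ignore.strand = TRUE)
        mcols(g)$regionType <- ifelse(mcols(g)$nCpg >=
                                      cfg@umrLmrCpgThreshold, "UMR", "LMR")
        mcols(g)$sizeBp <- width(g)
    } else {
        mcols(g)$regionType <- character(0)
        mcols(g)$sizeBp <- integer(0)
    }
    RegionSet(g)
}

# region count on a permuted (null) methylome at fixed cutoffs; used by the
# FDR-control diagnostics and tests
nullRegionCount <- function(methylome, m, nMin, window = 3, seed = 1) {
    set.seed(as.integer(seed))
    byChrom <- perChromosome(methylome)
    total <- 0L
    for (ch in names(byChrom)) {
        sm <- smoothFractions(sample(byChrom[[ch]]$fraction), window)
        runs <- lowRuns(sm, m)
        total <- total +
            sum(runs[, "end"] - runs[, "start"] + 1L >= nMin)
    }
    total
}
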