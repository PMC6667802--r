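#' Overlap width of two genomic intervals
#'
#' Length in bp of the intersection of two intervals; 0 when they lie on
#' different chromosomes or merely abut. Symmetric in its arguments, and
#' \code{overlapBp(a, a)} equals the width of \code{a}.
#'
#' @param a,b length-1 \link[GenomicRanges]{GRanges}.
#' @return Integer overlap width in bp.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' overlapBp(a, b)  # 50
#' @export
overlapBp <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        return(0L)
    w <- min(end(a), end(b)) - max(start(a), start(b)) + 1L
    max(0L, as.integer(w))
}

#' Majority-overlap assignment of a query interval to a target
#'
#' Returns the index of the target interval covering more than half of the
#' query's length, or \code{NA} when none does (an exact 50/50 tie assigns
#' nothing). Targets must be pairwise non-overlapping so at most one target
#' can qualify.
#'
#' @param query length-1 GRanges.
#' @param targets GRanges of pairwise disjoint intervals.
#' @param rule \code{"majority"} (>50\% of the query), \code{"any"}
#'   (any positive overlap; the largest wins), or \code{"containment"}
#'   (the query must lie entirely inside the target).
#' @return Integer index into \code{targets}, or \code{NA_integer_}.
#' @examples
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 61), c(60, 200)))
#' majorityOverlap(q, t)  # 1 (60% cover)
#' @export
majorityOverlap <- function(query, targets, rule = "majority") {
    stopifnot(length(query) == 1L)
    if (length(targets) == 0L)
        return(NA_integer_)
    ov <- findOverlaps(targets, drop.self = TRUE, drop.redundant = TRUE,
                       ignore.strand = TRUE)
    if (length(ov))
        stop("targets must be pairwise non-overlapping")
    hits <- suppressWarnings(findOverlaps(query, targets,
                                          ignore.strand = TRUE))
    if (!length(hits))
        return(NA_integer_)
    idx <- subjectHits(hits)
    w <- width(pintersect(rep(query, length(idx)), targets[idx]))
    best <- which.max(w)
    if (rule == "any")
        return(idx[best])
    if (rule == "containment") {
        if (w[best] == width(query)) return(idx[best])
        return(NA_integer_)
    }
    if (w[best] * 2L > width(query)) idx[best] else NA_integer_
}

# stable per-stage sub-seed derived from the master seed; keeps every
# randomized stage independent yet reproducible from one config seed
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

# split a Methylome into per-chromosome position/fraction lists
perChromosome <- function(methylome) {
    s <- methSites(methylome)
    fr <- methFraction(methylome)
    chr <- as.character(seqnames(s))
    pos <- start(s)
    idx <- split(seq_along(pos), chr)
    lapply(idx, function(i) list(pos = pos[i], fraction = fr[i],
                                 countMeth = mcols(s)$countMeth[i],
                                 countTotal = mcols(s)$countTotal[i]))
}

#' Drop low-coverage CpG sites
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param minCov minimum \code{countTotal} to retain a site.
#' @return A filtered \linkS4class{Methylome}.
#' @export
filterCoverage <- function(methylome, minCov = 5) {
    s <- methSites(methylome)
    keep <- mcols(s)$countTotal >= minCov
    Methylome(sampleId(methylome), s[keep])
}
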