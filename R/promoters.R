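#' Extract promoter windows from gene models
#'
#' One promoter per distinct TSS. On the plus strand the window covers
#' \code{upstream} bp before the TSS and \code{downstream} bp from the TSS
#' on; minus-strand windows are mirrored. Windows are clamped to
#' chromosome bounds when lengths are supplied.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param upstream,downstream window extents in bp (defaults 1000 and 200).
#' @param chromLengths optional named vector for clamping.
#' @return GRanges of promoters with \code{geneId}, \code{transcriptId} and
#'   \code{tss} metadata columns (strand set from the transcript).
#' @export
extractPromoters <- function(geneModels, upstream = 1000, downstream = 200,
                             chromLengths = NULL) {
    tt <- transcriptTable(geneModels)
    plus <- tt$strand == "+"
    start <- ifelse(plus, tt$tss - upstream, tt$tss - downstream)
    end <- ifelse(plus, tt$tss + downstream - 1, tt$tss + upstream - 1)
    start <- pmax(start, 1)
    if (!is.null(chromLengths))
        end <- pmin(end, chromLengths[tt$chrom])
    g <- GRanges(tt$chrom, IRanges(start, end), strand = tt$strand,
                 geneId = tt$geneId, transcriptId = tt$transcriptId,
                 tss = tt$tss)
    # one promoter per distinct TSS within a gene
    key <- paste(tt$geneId, tt$chrom, tt$tss, tt$strand)
    g[!duplicated(key)]
}

#' Mean promoter methylation
#'
#' Unweighted mean of the per-CpG percent methylation (fraction x 100)
#' over covered CpGs falling in the interval; \code{NA} when no CpG is
#' covered.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param interval length-1 GRanges.
#' @return List with \code{meanMethPct} and \code{nCpgCovered}.
#' @export
promoterMeanMethylation <- function(methylome, interval) {
    s <- methSites(methylome)
    hit <- findOverlaps(interval, s, ignore.strand = TRUE)
    idx <- subjectHits(hit)
    if (!length(idx))
        return(list(meanMethPct = NA_real_, nCpgCovered = 0L))
    fr <- methFraction(methylome)[idx]
    list(meanMethPct = 100 * mean(fr), nCpgCovered = length(idx))
}

checkTiling <- function(segGr, chrom) {
    g <- segGr[as.character(seqnames(segGr)) == chrom]
    if (!length(g))
        stop("no segments on chromosome ", chrom)
    o <- order(start(g))
    if (any(start(g)[o][-1] <= end(g)[o][-length(g)]))
        stop("segments overlap on chromosome ", chrom)
    invisible(TRUE)
}

#' Classify promoters against methylome states
#'
#' Applies the hypermethylation rule to every promoter: the promoter is
#' hypermethylated when (i) the segment it is located in (majority overlap
#' by default) has segmentation class 3 or 4, and (ii) no called UMR or
#' LMR larger than \code{cfg@regionSizeFilterBp} (500 bp) overlaps the
#' promoter. Any positive overlap counts for the blocking test, while
#' location uses \code{cfg@overlapRule}.
#'
#' @param promoters GRanges from \code{\link{extractPromoters}}.
#' @param segmentSet a \linkS4class{SegmentSet} with classes assigned.
#' @param regionSet a \linkS4class{RegionSet} of UMR/LMR calls.
#' @param methylome a \linkS4class{Methylome}.
#' @param cfg a \linkS4class{MethylConfig}.
#' @return data.frame (one row per promoter): \code{geneId},
#'   \code{transcriptId}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{tss}, \code{meanMethPct}, \code{nCpgCovered},
#'   \code{locatedClass}, \code{locatedSegWidth}, \code{nBlockingRegions},
#'   \code{maxOverlapRegionWidth}, \code{hypermethylated}.
#' @export
callPromoters <- function(promoters, segmentSet, regionSet, methylome,
                          cfg = methylConfig()) {
    segGr <- segments(segmentSet)
    regGr <- regions(regionSet)
    regGr <- regGr[mcols(regGr)$regionType %in% c("UMR", "LMR")]
    for (ch in unique(as.character(seqnames(promoters))))
        checkTiling(segGr, ch)
    n <- length(promoters)
    locatedClass <- integer(n); locatedWidth <- numeric(n)
    nBlock <- integer(n); maxRegW <- numeric(n)
    meanPct <- numeric(n); nCov <- integer(n)
    for (i in seq_len(n)) {
        p <- promoters[i]
        j <- majorityOverlap(p, segGr, rule = cfg@overlapRule)
        locatedClass[i] <- if (is.na(j)) NA_integer_
                           else mcols(segGr)$segClass[j]
        locatedWidth[i] <- if (is.na(j)) NA_real_ else width(segGr[j])
        hit <- findOverlaps(p, regGr, ignore.strand = TRUE)
        rw <- width(regGr)[subjectHits(hit)]
        maxRegW[i] <- if (length(rw)) max(rw) else 0
        nBlock[i] <- sum(rw > cfg@regionSizeFilterBp)
        mm <- promoterMeanMethylation(methylome, p)
        meanPct[i] <- mm$meanMethPct
        nCov[i] <- mm$nCpgCovered
    }
    hyper <- !is.na(locatedClass) & locatedClass %in% c(3L, 4L) &
        nBlock == 0L
    data.frame(geneId = mcols(promoters)$geneId,
               transcriptId = mcols(promoters)$transcriptId,
               chrom = as.character(seqnames(promoters)),
               start = start(promoters), end = end(promoters),
               strand = as.character(strand(promoters)),
               tss = mcols(promoters)$tss,
               meanMethPct = meanPct, nCpgCovered = nCov,
               locatedClass = locatedClass,
               locatedSegWidth = locatedWidth,
               nBlockingRegions = nBlock,
               maxOverlapRegionWidth = maxRegW,
               hypermethylated = hyper)
}

#' Select representative promoters and call genes
#'
#' For each gene, among the promoters whose assigned segment or an
#' overlapping UMR/LMR spans more than \code{minSpan} bp (and that cover at
#' least one CpG), the promoter with the lowest mean percent methylation is
#' the representative (ties go to the 5'-most TSS in transcript
#' orientation). A gene is hypermethylated when every one of its promoters
#' is.
#'
#' @param promoterCalls data.frame from \code{\link{callPromoters}}.
#' @param minSpan minimum qualifying span in bp (default 500).
#' @return data.frame (one row per gene): \code{geneId},
#'   \code{representativeTranscript} (NA when no promoter qualifies),
#'   \code{representativeMeanMethPct}, \code{nPromoters},
#'   \code{geneHypermethylated}.
#' @export
selectRepresentative <- function(promoterCalls, minSpan = 500) {
    if (!nrow(promoterCalls)) stop("no promoter calls supplied")
    byGene <- split(seq_len(nrow(promoterCalls)), promoterCalls$geneId)
    rows <- lapply(names(byGene), function(gid) {
        d <- promoterCalls[byGene[[gid]], , drop = FALSE]
        segW <- ifelse(is.na(d$locatedSegWidth), 0, d$locatedSegWidth)
        qual <- (segW > minSpan | d$maxOverlapRegionWidth > minSpan) &
            !is.na(d$meanMethPct)
        rep <- NA_integer_
        if (any(qual)) {
            q <- which(qual)
            best <- q[d$meanMethPct[q] == min(d$meanMethPct[q])]
            if (length(best) > 1) {   # tie: 5'-most TSS
                tss <- d$tss[best]
                best <- if (d$strand[best[1]] == "-")
                    best[which.max(tss)] else best[which.min(tss)]
            } else best <- best[1]
            rep <- best
        }
        data.frame(geneId = gid,
                   representativeTranscript = if (is.na(rep))
                       NA_character_ else d$transcriptId[rep],
                   representativeMeanMethPct = if (is.na(rep)) NA_real_
                       else d$meanMethPct[rep],
                   nPromoters = nrow(d),
                   geneHypermethylated = all(d$hypermethylated))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Percentage of hypermethylated genes in a gene set
#'
#' 100 x (hypermethylated genes in the set) / (set genes present in the
#' annotation). Genes absent from the annotation are excluded from the
#' denominator with a warning; an empty intersection is an error.
#'
#' @param geneCalls data.frame from \code{\link{selectRepresentative}}.
#' @param geneSet character vector of gene ids.
#' @return Numeric percentage in [0, 100].
#' @export
geneSetPercentage <- function(geneCalls, geneSet) {
    present <- geneSet %in% geneCalls$geneId
    if (!any(present))
        stop("no gene of the set is present in the annotation")
    if (!all(present))
        warning(sum(!present), " gene(s) of the set absent from the ",
                "annotation; excluded from the denominator")
    gs <- geneSet[present]
    hyper <- geneCalls$geneHypermethylated[match(gs, geneCalls$geneId)]
    100 * sum(hyper) / length(gs)
}

#' Build a genes-by-samples methylation heatmap matrix
#'
#' Cells hold each gene's representative promoter mean percent methylation
#' per sample; \code{NA} where no promoter qualifies. Column order follows
#' the order of \code{geneCallsList}.
#'
#' @param geneCallsList named list of gene-call data.frames (one per
#'   sample).
#' @param genes character vector of gene ids (row order).
#' @return Numeric matrix with genes as rows and samples as columns.
#' @export
buildHeatmapMatrix <- function(geneCallsList, genes) {
    m <- vapply(geneCallsList, function(gc)
        gc$representativeMeanMethPct[match(genes, gc$geneId)],
        numeric(length(genes)))
    m <- matrix(m, nrow = length(genes),
                dimnames = list(genes, names(geneCallsList)))
    m
}

#' Per-CpG methylation profile around a TSS
#'
#' Collects the percent methylation of each covered CpG in the union of
#' the promoter window and the first exon, with signed offsets from the
#' TSS oriented in transcript direction (negative = upstream). CpGs in the
#' overlap of promoter and first exon are counted once.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param promoter length-1 GRanges with \code{tss} metadata and strand.
#' @param firstExon length-1 GRanges (strand ignored; taken from promoter).
#' @return List with \code{profile} (data.frame \code{offset}, \code{pct})
#'   sorted by offset, and \code{meanPct} over all covered CpGs in the
#'   union.
#' @export
cpgProfile <- function(methylome, promoter, firstExon) {
    un <- reduce(c(granges(promoter), granges(firstExon)),
                 ignore.strand = TRUE)
    s <- methSites(methylome)
    hit <- findOverlaps(un, s, ignore.strand = TRUE)
    idx <- sort(unique(subjectHits(hit)))
    if (!length(idx))
        return(list(profile = data.frame(offset = integer(0),
                                         pct = numeric(0)),
                    meanPct = NA_real_))
    pos <- start(s)[idx]
    tss <- mcols(promoter)$tss
    off <- if (as.character(strand(promoter)) == "-") tss - pos
           else pos - tss
    pct <- 100 * methFraction(methylome)[idx]
    o <- order(off)
    list(profile = data.frame(offset = off[o], pct = pct[o]),
         meanPct = mean(pct))
}
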