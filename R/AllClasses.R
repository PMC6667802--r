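#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps pintersect reduce sort mcols
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits Rle DataFrame metadata
#'   metadata<- mcols<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration for the methylome-state pipeline
#'
#' Holds every tunable of the pipeline: segmentation, UMR/LMR calling,
#' PMD detection and promoter classification. All thresholds must be
#' positive and \code{fdrTarget} must lie in (0,1).
#'
#' @slot kClasses integer, number of ordered segmentation classes (default 4).
#' @slot minCpgPerSegment integer, minimum CpGs per segment (default 10).
#' @slot cpPenalty numeric, change-point penalty multiplier; a split is
#'   accepted when the drop in within-segment sum of squares exceeds
#'   \code{cpPenalty * log(n)} with \code{n} the chromosome CpG count.
#' @slot smoothWindow odd integer, running-mean window in CpGs (default 3).
#' @slot mGrid numeric vector, methylation cutoffs for the FDR grid.
#' @slot nGrid integer vector, minimum run lengths (CpGs) for the FDR grid.
#' @slot fdrTarget numeric in (0,1), target false discovery rate (default 0.05).
#' @slot nPerm integer, permutations per grid point (default 10).
#' @slot umrLmrCpgThreshold integer, CpG count separating UMR from LMR
#'   (default 30).
#' @slot regionSizeFilterBp numeric, regions larger than this (bp) block a
#'   promoter from being called hypermethylated (default 500).
#' @slot promoterUpstream,promoterDownstream numeric, promoter window around
#'   the TSS in bp (defaults 1000 and 200).
#' @slot minCov integer, minimum read coverage per CpG (default 5).
#' @slot overlapRule character, how a promoter is assigned to a segment:
#'   \code{"majority"} (default, >50\% of promoter length), \code{"any"}, or
#'   \code{"containment"}.
#' @slot pmdEnabled logical, run the PMD HMM stage (default FALSE).
#' @slot pmdMinLenBp numeric, minimum PMD length in bp (default 10000).
#' @slot rngSeed integer seed driving all randomized stages.
#' @export
setClass("MethylConfig", representation(
    kClasses = "integer",
    minCpgPerSegment = "integer",
    cpPenalty = "numeric",
    smoothWindow = "integer",
    mGrid = "numeric",
    nGrid = "integer",
    fdrTarget = "numeric",
    nPerm = "integer",
    umrLmrCpgThreshold = "integer",
    regionSizeFilterBp = "numeric",
    promoterUpstream = "numeric",
    promoterDownstream = "numeric",
    minCov = "integer",
    overlapRule = "character",
    pmdEnabled = "logical",
    pmdMinLenBp = "numeric",
    rngSeed = "integer"
))

setValidity("MethylConfig", function(object) {
    msg <- character()
    pos <- c(kClasses = object@kClasses,
             minCpgPerSegment = object@minCpgPerSegment,
             cpPenalty = object@cpPenalty,
             smoothWindow = object@smoothWindow,
             umrLmrCpgThreshold = object@umrLmrCpgThreshold,
             regionSizeFilterBp = object@regionSizeFilterBp,
             promoterUpstream = object@promoterUpstream,
             promoterDownstream = object@promoterDownstream,
             minCov = object@minCov,
             pmdMinLenBp = object@pmdMinLenBp)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("thresholds must be positive: ",
                             paste(bad, collapse = ", ")))
    if (!is.finite(object@fdrTarget) ||
        object@fdrTarget <= 0 || object@fdrTarget >= 1)
        msg <- c(msg, "fdrTarget must lie in (0,1)")
    if (object@smoothWindow %% 2L != 1L)
        msg <- c(msg, "smoothWindow must be odd")
    if (object@nPerm < 0L)
        msg <- c(msg, "nPerm must be non-negative")
    if (!object@overlapRule %in% c("majority", "any", "containment"))
        msg <- c(msg, "overlapRule must be majority, any or containment")
    if (any(object@mGrid <= 0 | object@mGrid >= 1))
        msg <- c(msg, "mGrid cutoffs must lie in (0,1)")
    if (any(object@nGrid < 1L))
        msg <- c(msg, "nGrid run lengths must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' @param kClasses,minCpgPerSegment,cpPenalty,smoothWindow,mGrid,nGrid,fdrTarget
#'   see the corresponding \linkS4class{MethylConfig} slots.
#' @param nPerm,umrLmrCpgThreshold,regionSizeFilterBp,promoterUpstream
#'   see the corresponding slots.
#' @param promoterDownstream,minCov,overlapRule,pmdEnabled,pmdMinLenBp,rngSeed
#'   see the corresponding slots.
#' @return A validated \linkS4class{MethylConfig}.
#' @examples
#' cfg <- methylConfig()
#' cfg
#' @export
methylConfig <- function(kClasses = 4, minCpgPerSegment = 10,
                         cpPenalty = 0.1, smoothWindow = 3,
                         mGrid = c(0.3, 0.4, 0.5, 0.6, 0.7),
                         nGrid = 2:20, fdrTarget = 0.05, nPerm = 10,
                         umrLmrCpgThreshold = 30, regionSizeFilterBp = 500,
                         promoterUpstream = 1000, promoterDownstream = 200,
                         minCov = 5, overlapRule = "majority",
                         pmdEnabled = FALSE, pmdMinLenBp = 10000,
                         rngSeed = 1) {
    new("MethylConfig",
        kClasses = as.integer(kClasses),
        minCpgPerSegment = as.integer(minCpgPerSegment),
        cpPenalty = as.numeric(cpPenalty),
        smoothWindow = as.integer(smoothWindow),
        mGrid = as.numeric(mGrid),
        nGrid = as.integer(nGrid),
        fdrTarget = as.numeric(fdrTarget),
        nPerm = as.integer(nPerm),
        umrLmrCpgThreshold = as.integer(umrLmrCpgThreshold),
        regionSizeFilterBp = as.numeric(regionSizeFilterBp),
        promoterUpstream = as.numeric(promoterUpstream),
        promoterDownstream = as.numeric(promoterDownstream),
        minCov = as.integer(minCov),
        overlapRule = overlapRule,
        pmdEnabled = isTRUE(pmdEnabled),
        pmdMinLenBp = as.numeric(pmdMinLenBp),
        rngSeed = as.integer(rngSeed))
}

#' Per-CpG methylome for one sample
#'
#' Position-sorted per-CpG methylation counts in CpG context. Sites are
#' width-1 \link[GenomicRanges]{GRanges} at the forward-strand cytosine with
#' metadata columns \code{countMeth} and \code{countTotal}; the methylation
#' fraction is \code{countMeth / countTotal}.
#'
#' @slot sampleId character scalar naming the sample.
#' @slot sites width-1 GRanges, sorted, no duplicate positions, with
#'   integer metadata columns \code{countMeth} and \code{countTotal}
#'   (\code{0 <= countMeth <= countTotal}, \code{countTotal > 0}).
#' @export
setClass("Methylome", representation(sampleId = "character",
                                     sites = "GRanges"))

setValidity("Methylome", function(object) {
    msg <- character()
    s <- object@sites
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    mc <- mcols(s)
    if (!all(c("countMeth", "countTotal") %in% colnames(mc)))
        return("sites need countMeth and countTotal metadata columns")
    if (length(s)) {
        if (any(width(s) != 1L))
            msg <- c(msg, "sites must have width 1")
        cm <- mc$countMeth; ct <- mc$countTotal
        if (any(cm < 0L) || any(ct <= 0L) || any(cm > ct))
            msg <- c(msg, "need 0 <= countMeth <= countTotal and countTotal > 0")
        if (S4Vectors::isSorted(s) == FALSE)
            msg <- c(msg, "sites must be position-sorted")
        key <- paste(as.character(seqnames(s)), start(s))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos) sites")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Methylome
#'
#' @param sampleId sample name.
#' @param sites width-1 GRanges with \code{countMeth}/\code{countTotal}
#'   metadata columns; sorted automatically.
#' @return A \linkS4class{Methylome}.
#' @export
Methylome <- function(sampleId, sites) {
    sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
    GenomicRanges::strand(sites) <- "*"
    new("Methylome", sampleId = as.character(sampleId), sites = sites)
}

#' Contiguous genome segmentation with ordered classes
#'
#' A per-chromosome tiling of the CpG sequence into segments, each carrying
#' its CpG count, mean methylation fraction and (once assigned) an ordered
#' segmentation class in \code{1..k}; class centers increase with the label,
#' so classes 3 and 4 of a 4-class run are the high-methylation states.
#'
#' @slot segments GRanges with metadata columns \code{nCpg}, \code{meanMeth}
#'   and \code{segClass} (NA until classes are assigned).
#' @export
setClass("SegmentSet", representation(segments = "GRanges"))

setValidity("SegmentSet", function(object) {
    g <- object@segments
    mc <- mcols(g)
    if (!all(c("nCpg", "meanMeth", "segClass") %in% colnames(mc)))
        return("segments need nCpg, meanMeth and segClass metadata columns")
    msg <- character()
    if (length(g)) {
        if (any(mc$meanMeth < 0 | mc$meanMeth > 1, na.rm = TRUE))
            msg <- c(msg, "meanMeth must lie in [0,1]")
        if (!S4Vectors::isSorted(g))
            msg <- c(msg, "segments must be sorted")
        ov <- findOverlaps(g, drop.self = TRUE, drop.redundant = TRUE,
                           ignore.strand = TRUE)
        if (length(ov))
            msg <- c(msg, "segments of one chromosome must not overlap")
    }
    if (length(msg)) msg else TRUE
})

SegmentSet <- function(segments) new("SegmentSet", segments = segments)

#' Called discrete methylome regions (UMR, LMR, PMD)
#'
#' @slot regions GRanges with metadata columns \code{nCpg}, \code{meanMeth},
#'   \code{regionType} (one of UMR, LMR, PMD) and \code{sizeBp}.
#' @export
setClass("RegionSet", representation(regions = "GRanges"))

setValidity("RegionSet", function(object) {
    g <- object@regions
    mc <- mcols(g)
    if (!all(c("nCpg", "meanMeth", "regionType", "sizeBp") %in% colnames(mc)))
        return("regions need nCpg, meanMeth, regionType, sizeBp columns")
    msg <- character()
    if (length(g)) {
        if (!all(mc$regionType %in% c("UMR", "LMR", "PMD")))
            msg <- c(msg, "regionType must be UMR, LMR or PMD")
        if (any(mc$sizeBp != width(g)))
            msg <- c(msg, "sizeBp must equal region width")
        keep <- mc$regionType %in% c("UMR", "LMR")
        if (sum(keep) > 1) {
            ov <- findOverlaps(g[keep], drop.self = TRUE,
                               drop.redundant = TRUE, ignore.strand = TRUE)
            if (length(ov))
                msg <- c(msg, "UMR/LMR regions must be pairwise disjoint")
        }
    }
    if (length(msg)) msg else TRUE
})

RegionSet <- function(regions) new("RegionSet", regions = regions)

#' Gene models (transcripts with exon structure)
#'
#' @slot exons GRanges of exons with metadata columns \code{geneId} and
#'   \code{transcriptId}; strand is meaningful.
#' @export
setClass("GeneModels", representation(exons = "GRanges"))

setValidity("GeneModels", function(object) {
    mc <- mcols(object@exons)
    if (!all(c("geneId", "transcriptId") %in% colnames(mc)))
        return("exons need geneId and transcriptId metadata columns")
    if (length(object@exons) &&
        any(!as.character(strand(object@exons)) %in% c("+", "-")))
        return("exon strand must be + or -")
    TRUE
})

GeneModels <- function(exons) new("GeneModels", exons = exons)

#' Two-state HMM parameters with Beta emissions
#'
#' State 1 is the fully-methylated background (mean near 0.85, concentrated),
#' state 2 the partially methylated domain (mean near 0.5, diffuse).
#'
#' @slot initProb length-2 initial state distribution.
#' @slot transMat 2x2 row-stochastic transition matrix.
#' @slot shape1,shape2 length-2 Beta shape parameters per state.
#' @export
setClass("HmmParams", representation(initProb = "numeric",
                                     transMat = "matrix",
                                     shape1 = "numeric",
                                     shape2 = "numeric"))

setValidity("HmmParams", function(object) {
    msg <- character()
    if (length(object@initProb) != 2L ||
        abs(sum(object@initProb) - 1) > 1e-8 || any(object@initProb < 0))
        msg <- c(msg, "initProb must be a length-2 distribution")
    if (!all(dim(object@transMat) == c(2L, 2L)) ||
        any(abs(rowSums(object@transMat) - 1) > 1e-8) ||
        any(object@transMat < 0))
        msg <- c(msg, "transMat must be 2x2 row-stochastic")
    if (length(object@shape1) != 2L || length(object@shape2) != 2L ||
        any(c(object@shape1, object@shape2) <= 0))
        msg <- c(msg, "Beta shapes must be positive length-2 vectors")
    if (length(msg)) msg else TRUE
})

#' Construct HMM parameters
#'
#' @param initProb,transMat,shape1,shape2 see \linkS4class{HmmParams}.
#' @return An \linkS4class{HmmParams}.
#' @export
hmmParams <- function(initProb, transMat, shape1, shape2) {
    new("HmmParams", initProb = initProb, transMat = transMat,
        shape1 = shape1, shape2 = shape2)
}

#' Default PMD HMM parameterization
#'
#' Background state: Beta mean 0.85, concentration 20; PMD state: mean 0.5,
#' concentration 4. Transitions favour long dwell times so that domains span
#' hundreds of CpGs.
#' @return An \linkS4class{HmmParams}.
#' @export
defaultHmmParams <- function() {
    hmmParams(initProb = c(0.99, 0.01),
              transMat = matrix(c(0.9995, 0.0005, 0.002, 0.998),
                                nrow = 2, byrow = TRUE),
              shape1 = c(0.85 * 20, 0.5 * 4),
              shape2 = c(0.15 * 20, 0.5 * 4))
}

#' Simulation design for synthetic bisulfite methylomes
#'
#' Describes the genomic landscape the generator emulates: CpG spacing
#' (sparse background, dense islands), the Beta emission of each methylome
#' state, sequencing coverage, overdispersion, gene/gene-set layout and the
#' two-condition promoter methylation map (progenitor-like samples carry
#' fully methylated photoreceptor promoters; photoreceptor-like samples the
#' same promoters demethylated).
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot bgSpacing mean background CpG spacing in bp.
#' @slot islandSpacing mean CpG spacing inside island (promoter/UMR/LMR)
#'   slots in bp.
#' @slot stateMeans,stateConcs named numeric over FMR/UMR/LMR/PMD: Beta
#'   emission mean and concentration per methylome state.
#' @slot coverageLambda Poisson mean read coverage per CpG.
#' @slot rho beta-binomial overdispersion (0 = exact binomial).
#' @slot nPhotoreceptorGenes integer, genes in the photoreceptor set.
#' @slot otherSets named integer, sizes of non-photoreceptor gene sets.
#' @slot nExtraUmr,nExtraLmr integer, intergenic UMR/LMR slots.
#' @slot nPmd integer, planted PMDs (0 by default).
#' @slot geneSlotLenRange,umrLenRange,lmrLenRange,pmdLenRange length ranges
#'   (bp) for the planted region slots.
#' @export
setClass("SimDesign", representation(
    chromLengths = "numeric",
    bgSpacing = "numeric",
    islandSpacing = "numeric",
    stateMeans = "numeric",
    stateConcs = "numeric",
    coverageLambda = "numeric",
    rho = "numeric",
    nPhotoreceptorGenes = "integer",
    otherSets = "integer",
    nExtraUmr = "integer",
    nExtraLmr = "integer",
    nPmd = "integer",
    geneSlotLenRange = "numeric",
    umrLenRange = "numeric",
    lmrLenRange = "numeric",
    pmdLenRange = "numeric"
))

setValidity("SimDesign", function(object) {
    msg <- character()
    if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be named and positive")
    st <- c("FMR", "UMR", "LMR", "PMD")
    if (!all(st %in% names(object@stateMeans)) ||
        !all(st %in% names(object@stateConcs)))
        msg <- c(msg, "stateMeans/stateConcs need FMR, UMR, LMR, PMD entries")
    if (any(object@stateMeans <= 0 | object@stateMeans >= 1))
        msg <- c(msg, "state means must lie in (0,1)")
    if (object@coverageLambda <= 0)
        msg <- c(msg, "coverageLambda must be positive")
    if (object@rho < 0 || object@rho >= 1)
        msg <- c(msg, "rho must lie in [0,1)")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation design
#'
#' Defaults mirror a mammalian-retina-like landscape: high-methylation
#' background (Beta mean 0.85), CpG-island promoters, ~20x Poisson coverage
#' with mild beta-binomial overdispersion, a 12-gene photoreceptor set and a
#' 40-gene non-photoreceptor set on a 2 Mb chromosome.
#'
#' @param chromLengths,bgSpacing,islandSpacing see \linkS4class{SimDesign}.
#' @param stateMeans,stateConcs,coverageLambda,rho see \linkS4class{SimDesign}.
#' @param nPhotoreceptorGenes,otherSets,nExtraUmr,nExtraLmr,nPmd see
#'   \linkS4class{SimDesign}.
#' @param geneSlotLenRange,umrLenRange,lmrLenRange,pmdLenRange see
#'   \linkS4class{SimDesign}.
#' @return A \linkS4class{SimDesign}.
#' @examples
#' des <- simDesign(chromLengths = c(chr1 = 2e5), nPhotoreceptorGenes = 2,
#'                  otherSets = c(non_photoreceptor = 4))
#' @export
simDesign <- function(chromLengths = c(chr1 = 2e6),
                      bgSpacing = 100, islandSpacing = 10,
                      stateMeans = c(FMR = 0.85, UMR = 0.05,
                                     LMR = 0.30, PMD = 0.50),
                      stateConcs = c(FMR = 20, UMR = 20, LMR = 20, PMD = 4),
                      coverageLambda = 20, rho = 0.05,
                      nPhotoreceptorGenes = 12,
                      otherSets = c(non_photoreceptor = 40),
                      nExtraUmr = 10, nExtraLmr = 20, nPmd = 0,
                      geneSlotLenRange = c(2000, 5000),
                      umrLenRange = c(1000, 5000),
                      lmrLenRange = c(300, 1000),
                      pmdLenRange = c(50000, 200000)) {
    os <- as.integer(otherSets); names(os) <- names(otherSets)
    new("SimDesign", chromLengths = chromLengths, bgSpacing = bgSpacing,
        islandSpacing = islandSpacing, stateMeans = stateMeans,
        stateConcs = stateConcs, coverageLambda = coverageLambda, rho = rho,
        nPhotoreceptorGenes = as.integer(nPhotoreceptorGenes),
        otherSets = os, nExtraUmr = as.integer(nExtraUmr),
        nExtraLmr = as.integer(nExtraLmr), nPmd = as.integer(nPmd),
        geneSlotLenRange = geneSlotLenRange, umrLenRange = umrLenRange,
        lmrLenRange = lmrLenRange, pmdLenRange = pmdLenRange)
}

#' Simulator ground truth
#'
#' @slot regions GRanges tiling each simulated chromosome with metadata
#'   columns \code{trueState} (FMR/UMR/LMR/PMD) and \code{trueMean}.
#' @slot siteProbs width-1 GRanges of CpG sites with metadata column
#'   \code{p}, the true per-CpG methylation probability.
#' @slot intendedCalls data.frame with columns \code{geneId},
#'   \code{condition}, \code{hypermethylated}: the planted per-gene verdict.
#' @export
setClass("TruthTable", representation(regions = "GRanges",
                                      siteProbs = "GRanges",
                                      intendedCalls = "data.frame"))

#' FDR calibration grid result
#'
#' @slot grid data.frame with columns \code{m}, \code{n}, \code{observed},
#'   \code{randomizedMean}, \code{fdr}.
#' @slot mStar,nStar selected methylation cutoff and minimum run length.
#' @slot fdrTarget the target rate used for selection.
#' @export
setClass("FdrGridResult", representation(grid = "data.frame",
                                         mStar = "numeric",
                                         nStar = "integer",
                                         fdrTarget = "numeric"))

# ---- show methods ----

setMethod("show", "MethylConfig", function(object) {
    cat("MethylConfig:",
        sprintf("k=%d, minCpg=%d, penalty=%g, window=%d, fdr=%g",
                object@kClasses, object@minCpgPerSegment, object@cpPenalty,
                object@smoothWindow, object@fdrTarget), "\n")
    cat(sprintf("  UMR/LMR split at %d CpGs; blocking region > %g bp;",
                object@umrLmrCpgThreshold, object@regionSizeFilterBp),
        sprintf("promoter -%g/+%g bp; minCov=%d; overlap=%s\n",
                object@promoterUpstream, object@promoterDownstream,
                object@minCov, object@overlapRule))
})

setMethod("show", "Methylome", function(object) {
    s <- object@sites
    cat(sprintf("Methylome '%s': %d CpG sites on %d chromosome(s)\n",
                object@sampleId, length(s),
                length(unique(as.character(seqnames(s))))))
    if (length(s)) {
        fr <- mcols(s)$countMeth / mcols(s)$countTotal
        cat(sprintf("  mean fraction %.3f, mean coverage %.1f\n",
                    mean(fr), mean(mcols(s)$countTotal)))
    }
})

setMethod("show", "SegmentSet", function(object) {
    g <- object@segments
    cat(sprintf("SegmentSet: %d segments", length(g)))
    if (length(g) && !all(is.na(mcols(g)$segClass))) {
        tab <- table(mcols(g)$segClass)
        cat(" | classes:", paste(names(tab), tab, sep = ":", collapse = " "))
    }
    cat("\n")
})

setMethod("show", "RegionSet", function(object) {
    g <- object@regions
    tab <- table(factor(mcols(g)$regionType, c("UMR", "LMR", "PMD")))
    cat(sprintf("RegionSet: %d regions (UMR %d, LMR %d, PMD %d)\n",
                length(g), tab["UMR"], tab["LMR"], tab["PMD"]))
})

setMethod("show", "GeneModels", function(object) {
    mc <- mcols(object@exons)
    cat(sprintf("GeneModels: %d genes, %d transcripts, %d exons\n",
                length(unique(mc$geneId)), length(unique(mc$transcriptId)),
                length(object@exons)))
})

setMethod("show", "HmmParams", function(object) {
    mu <- object@shape1 / (object@shape1 + object@shape2)
    cat(sprintf(
        "HmmParams: emission means %.3f / %.3f; stay probs %.4f / %.4f\n",
        mu[1], mu[2], object@transMat[1, 1], object@transMat[2, 2]))
})

setMethod("show", "FdrGridResult", function(object) {
    cat(sprintf(
        "FdrGridResult: %d grid points, selected m*=%.2f n*=%d (target %g)\n",
        nrow(object@grid), object@mStar, object@nStar, object@fdrTarget))
})

setMethod("show", "TruthTable", function(object) {
    cat(sprintf("TruthTable: %d planted regions, %d CpGs, %d gene calls\n",
                length(object@regions), length(object@siteProbs),
                nrow(object@intendedCalls)))
})
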