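#' Simulate the genomic layout of a synthetic methylome
#'
#' Generates clustered CpG positions (sparse background plus dense
#' CpG-island slots), gene models whose promoters coincide with plantable
#' region slots, and phenotype gene sets. Photoreceptor-set promoters are
#' placed on slots whose methylome state later depends on the condition;
#' all other promoters sit on slots planted as unmethylated regions.
#'
#' @param design a \linkS4class{SimDesign}.
#' @param seed integer seed; identical seeds give identical layouts.
#' @param promoterUpstream,promoterDownstream promoter window (bp) that must
#'   fit inside a gene's slot; defaults match the classifier's defaults.
#' @return A list with elements \code{chromLengths}, \code{cpgSites}
#'   (width-1 GRanges), \code{geneModels} (\linkS4class{GeneModels}),
#'   \code{geneSets} (named list) and \code{slots} (GRanges with
#'   \code{slotType}, \code{geneId}, \code{setName}).
#' @export
simulateLayout <- function(design, seed, promoterUpstream = 1000,
                           promoterDownstream = 200) {
    set.seed(as.integer(seed))
    chroms <- names(design@chromLengths)

    nOther <- sum(design@otherSets)
    geneIds <- character(0); geneSet <- character(0)
    if (design@nPhotoreceptorGenes > 0) {
        geneIds <- paste0("photo_g", seq_len(design@nPhotoreceptorGenes))
        geneSet <- rep("photoreceptor", design@nPhotoreceptorGenes)
    }
    for (nm in names(design@otherSets)) {
        k <- design@otherSets[[nm]]
        if (k > 0) {
            geneIds <- c(geneIds, paste0(nm, "_g", seq_len(k)))
            geneSet <- c(geneSet, rep(nm, k))
        }
    }
    nGenes <- length(geneIds)

    slotType <- c(rep("gene", nGenes),
                  rep("umr", design@nExtraUmr),
                  rep("lmr", design@nExtraLmr),
                  rep("pmd", design@nPmd))
    slotLen <- c(round(stats::runif(nGenes, design@geneSlotLenRange[1],
                                    design@geneSlotLenRange[2])),
                 round(stats::runif(design@nExtraUmr, design@umrLenRange[1],
                                    design@umrLenRange[2])),
                 round(stats::runif(design@nExtraLmr, design@lmrLenRange[1],
                                    design@lmrLenRange[2])),
                 round(stats::runif(design@nPmd, design@pmdLenRange[1],
                                    design@pmdLenRange[2])))
    slotGene <- c(geneIds, rep(NA_character_, length(slotType) - nGenes))
    slotSet <- c(geneSet, rep(NA_character_, length(slotType) - nGenes))

    # spread slots over chromosomes proportionally to length, then place
    # them left to right with randomized gaps and a minimum separation
    nSlots <- length(slotType)
    chromOf <- character(0)
    if (nSlots > 0) {
        shuffle <- sample.int(nSlots)
        slotType <- slotType[shuffle]; slotLen <- slotLen[shuffle]
        slotGene <- slotGene[shuffle]; slotSet <- slotSet[shuffle]
        alloc <- round(nSlots * design@chromLengths /
                       sum(design@chromLengths))
        while (sum(alloc) < nSlots) alloc[which.max(alloc)] <-
            alloc[which.max(alloc)] + 1L
        while (sum(alloc) > nSlots) alloc[which.max(alloc)] <-
            alloc[which.max(alloc)] - 1L
        chromOf <- rep(chroms, alloc)
    }
    margin <- 5000; minGap <- 2000
    slotStart <- integer(nSlots)
    for (ch in chroms) {
        idx <- which(chromOf == ch)
        if (!length(idx)) next
        span <- design@chromLengths[[ch]] - 2 * margin
        free <- span - sum(slotLen[idx]) - (length(idx) + 1) * minGap
        if (free < 0)
            stop("chromosome ", ch, " too short for requested slots/genes")
        u <- stats::runif(length(idx) + 1)
        gaps <- minGap + free * u / sum(u)
        starts <- margin + cumsum(gaps[seq_along(idx)]) +
            cumsum(c(0, slotLen[idx][-length(idx)]))
        slotStart[idx] <- round(starts)
    }
    slots <- GRanges(chromOf,
                     IRanges(start = if (nSlots) slotStart else integer(0),
                             width = slotLen),
                     slotType = slotType, geneId = slotGene,
                     setName = slotSet)
    slots <- GenomicRanges::sort(slots, ignore.strand = TRUE)

    # gene models: 1-3 transcripts per gene, TSSs inside the slot so that
    # every promoter window is contained in the plantable region
    exList <- list()
    gi <- which(mcols(slots)$slotType == "gene")
    for (i in gi) {
        gid <- mcols(slots)$geneId[i]
        chr <- as.character(seqnames(slots[i]))
        s0 <- start(slots[i]); e0 <- end(slots[i])
        str <- sample(c("+", "-"), 1)
        if (str == "+") {
            lo <- s0 + promoterUpstream; hi <- e0 - promoterDownstream + 1
        } else {
            lo <- s0 + promoterDownstream; hi <- e0 - promoterUpstream + 1
        }
        if (hi < lo) stop("gene slot too small for promoter window")
        nTx <- sample(1:3, 1)
        tss0 <- round(stats::runif(1, lo + min(100, (hi - lo) / 2),
                                   max(lo, hi - 100)))
        tss <- unique(pmin(hi, pmax(lo, c(tss0,
            tss0 + sample(c(-100:-10, 10:100), nTx - 1)))))
        for (j in seq_along(tss)) {
            tid <- paste0(gid, "_t", j)
            nEx <- sample(2:3, 1)
            if (str == "+") {
                st <- tss[j] + c(0, 500, 1200)[seq_len(nEx)]
                en <- st + c(199, 299, 199)[seq_len(nEx)]
            } else {
                en <- tss[j] - c(0, 500, 1200)[seq_len(nEx)]
                st <- en - c(199, 299, 199)[seq_len(nEx)]
            }
            exList[[length(exList) + 1L]] <-
                GRanges(chr, IRanges(st, en), strand = str,
                        geneId = gid, transcriptId = tid)
        }
    }
    geneModels <- if (length(exList))
        GeneModels(GenomicRanges::sort(do.call(c, exList),
                                       ignore.strand = TRUE))
    else GeneModels(GRanges(geneId = character(0),
                            transcriptId = character(0)))

    geneSets <- split(geneIds, geneSet)
    geneSets <- geneSets[unique(geneSet)]

    # CpG landscape: geometric spacings, dense inside island slots
    islandSlots <- slots[mcols(slots)$slotType %in% c("gene", "umr", "lmr")]
    cpgs <- lapply(chroms, function(ch) {
        len <- design@chromLengths[[ch]]
        nBg <- ceiling(len / design@bgSpacing * 1.3) + 100
        pos <- cumsum(1L + stats::rgeom(nBg, 1 / design@bgSpacing))
        pos <- pos[pos <= len - 1]
        isl <- islandSlots[seqnames(islandSlots) == ch]
        if (length(isl)) {
            inIsl <- overlapsAny(GRanges(ch, IRanges(pos, width = 1L)), isl)
            pos <- pos[!inIsl]
            for (k in seq_along(isl)) {
                w <- width(isl[k])
                nIs <- ceiling(w / design@islandSpacing * 1.5) + 20
                p <- start(isl[k]) - 1L +
                    cumsum(1L + stats::rgeom(nIs, 1 / design@islandSpacing))
                pos <- c(pos, p[p <= end(isl[k])])
            }
        }
        GRanges(ch, IRanges(sort(unique(pos)), width = 1L))
    })
    cpgSites <- do.call(c, cpgs)

    list(chromLengths = design@chromLengths, cpgSites = cpgSites,
         geneModels = geneModels, geneSets = geneSets, slots = slots)
}

#' Plant methylome states and per-CpG methylation probabilities
#'
#' Tiles each chromosome with state regions: in the progenitor-like
#' (\code{"RPC-like"}) condition photoreceptor-set promoter slots are fully
#' methylated (FMR, true mean >= 0.8); in the photoreceptor-like
#' (\code{"rod-like"}) condition the same slots are planted unmethylated.
#' Non-photoreceptor promoter slots are unmethylated in every condition.
#' Each CpG's true methylation probability is drawn from its containing
#' state's Beta emission.
#'
#' @param layout output of \code{\link{simulateLayout}}.
#' @param design the \linkS4class{SimDesign} used for the layout.
#' @param condition \code{"RPC-like"} or \code{"rod-like"}.
#' @param seed integer seed.
#' @return A \linkS4class{TruthTable}.
#' @export
plantStates <- function(layout, design, condition = c("RPC-like",
                                                      "rod-like"), seed) {
    condition <- match.arg(condition)
    set.seed(as.integer(seed))
    slots <- layout$slots
    slotState <- character(length(slots))
    for (i in seq_along(slots)) {
        ty <- mcols(slots)$slotType[i]
        if (ty == "gene") {
            photo <- identical(mcols(slots)$setName[i], "photoreceptor")
            slotState[i] <- if (photo && condition == "RPC-like") "FMR"
                            else "UMR"
        } else slotState[i] <- toupper(ty)
    }
    regs <- list()
    for (ch in names(layout$chromLengths)) {
        len <- layout$chromLengths[[ch]]
        sl <- slots[seqnames(slots) == ch]
        st <- slotState[as.character(seqnames(slots)) == ch]
        bounds <- c(1L, as.vector(rbind(start(sl), end(sl) + 1L)),
                    len + 1L)
        starts <- bounds[-length(bounds)]
        ends <- bounds[-1] - 1L
        states <- rep("FMR", length(starts))
        if (length(sl)) states[seq_along(sl) * 2] <- st
        keep <- ends >= starts
        regs[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]),
                              trueState = states[keep])
    }
    regions <- do.call(c, unname(regs))
    mcols(regions)$trueMean <- design@stateMeans[mcols(regions)$trueState]

    hit <- findOverlaps(layout$cpgSites, regions)
    stopifnot(length(hit) == length(layout$cpgSites))
    stateOf <- mcols(regions)$trueState[subjectHits(hit)]
    mu <- design@stateMeans[stateOf]; cc <- design@stateConcs[stateOf]
    p <- stats::rbeta(length(stateOf), mu * cc, (1 - mu) * cc)
    siteProbs <- layout$cpgSites
    mcols(siteProbs)$p <- p

    allGenes <- unlist(layout$geneSets, use.names = FALSE)
    photo <- allGenes %in% layout$geneSets[["photoreceptor"]]
    intended <- data.frame(geneId = allGenes,
                           condition = rep(condition, length(allGenes)),
                           hypermethylated = photo &
                               condition == "RPC-like")
    new("TruthTable", regions = regions, siteProbs = siteProbs,
        intendedCalls = intended)
}

#' Simulate bisulfite read counts for planted truth
#'
#' Coverage per CpG is Poisson(\code{coverageLambda}) with zero-coverage
#' sites dropped; methylated counts are binomial in the true probability, or
#' beta-binomial with overdispersion \code{rho} when \code{rho > 0}.
#'
#' @param truth a \linkS4class{TruthTable}.
#' @param design the \linkS4class{SimDesign}.
#' @param seed integer seed.
#' @param sampleId sample name for the result.
#' @return A \linkS4class{Methylome}.
#' @export
simulateCounts <- function(truth, design, seed, sampleId = "sim") {
    set.seed(as.integer(seed))
    sp <- truthSiteProbs(truth)
    p <- mcols(sp)$p
    cov <- stats::rpois(length(p), design@coverageLambda)
    keep <- cov > 0L
    p <- p[keep]; cov <- cov[keep]; sp <- sp[keep]
    if (design@rho > 0) {
        conc <- (1 - design@rho) / design@rho
        q <- ifelse(p <= 0 | p >= 1, p,
                    stats::rbeta(length(p), p * conc, (1 - p) * conc))
    } else q <- p
    meth <- stats::rbinom(length(q), cov, q)
    g <- granges(sp)
    mcols(g) <- NULL
    mcols(g)$countMeth <- meth
    mcols(g)$countTotal <- cov
    Methylome(sampleId, g)
}

#' Simulate a complete two-condition WGBS experiment
#'
#' One call yields everything the pipeline consumes: a progenitor-like
#' sample whose photoreceptor promoters are fully methylated and a
#' photoreceptor-like sample with those promoters demethylated, plus gene
#' models, gene sets and the per-condition ground truth.
#'
#' @param design a \linkS4class{SimDesign}.
#' @param seed integer master seed; stage sub-seeds are derived from it.
#' @return A list with \code{samples} (named \linkS4class{Methylome}s
#'   \code{"RPC-like"} and \code{"rod-like"}), \code{geneModels},
#'   \code{geneSets}, \code{truth} (named \linkS4class{TruthTable}s) and
#'   \code{layout}.
#' @export
simulateExperiment <- function(design, seed) {
    layout <- simulateLayout(design, deriveSeed(seed, "layout"))
    conds <- c("RPC-like", "rod-like")
    truth <- lapply(conds, function(cd)
        plantStates(layout, design, cd, deriveSeed(seed, paste0("plant_",
                                                                cd))))
    names(truth) <- conds
    samples <- lapply(conds, function(cd)
        simulateCounts(truth[[cd]], design,
                       deriveSeed(seed, paste0("counts_", cd)),
                       sampleId = cd))
    names(samples) <- conds
    list(samples = samples, geneModels = layout$geneModels,
         geneSets = layout$geneSets, truth = truth, layout = layout)
}
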