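CONFIG_KEYS <- c("k_classes", "min_cpg_per_segment", "cp_penalty",
                 "smooth_window", "m_grid", "n_grid", "fdr_target",
                 "n_perm", "umr_lmr_cpg_threshold", "region_size_filter_bp",
                 "promoter_upstream", "promoter_downstream", "min_cov",
                 "overlap_rule", "pmd_enabled", "pmd_min_len_bp")

DESIGN_KEYS <- c("chrom_lengths", "bg_spacing", "island_spacing",
                 "state_means", "state_concs", "coverage_lambda", "rho",
                 "n_photoreceptor_genes", "other_sets", "n_extra_umr",
                 "n_extra_lmr", "n_pmd", "gene_slot_len_range",
                 "umr_len_range", "lmr_len_range", "pmd_len_range")

#' Validate a pipeline YAML configuration
#'
#' The file must carry a top-level \code{seed}; optional \code{params} and
#' \code{design} blocks override \code{\link{methylConfig}} and
#' \code{\link{simDesign}} defaults (snake_case keys). Unknown keys and
#' invalid values are errors naming the offending key.
#'
#' @param configPath YAML file path.
#' @return List with \code{cfg} (\linkS4class{MethylConfig}),
#'   \code{design} (\linkS4class{SimDesign}), \code{seed} and \code{raw}
#'   (the parsed YAML).
#' @export
validateConfig <- function(configPath) {
    raw <- yaml::read_yaml(configPath)
    if (is.null(raw$seed))
        stop("config is missing required key 'seed'")
    unknownTop <- setdiff(names(raw), c("seed", "params", "design"))
    if (length(unknownTop))
        stop("unknown config key(s): ", paste(unknownTop, collapse = ", "))
    p <- raw$params
    if (!is.null(p)) {
        bad <- setdiff(names(p), CONFIG_KEYS)
        if (length(bad))
            stop("unknown params key(s): ", paste(bad, collapse = ", "))
    }
    getp <- function(key, default) if (is.null(p[[key]])) default
                                   else p[[key]]
    cfg <- methylConfig(
        kClasses = getp("k_classes", 4),
        minCpgPerSegment = getp("min_cpg_per_segment", 10),
        cpPenalty = getp("cp_penalty", 0.1),
        smoothWindow = getp("smooth_window", 3),
        mGrid = unlist(getp("m_grid", c(0.3, 0.4, 0.5, 0.6, 0.7))),
        nGrid = unlist(getp("n_grid", 2:20)),
        fdrTarget = getp("fdr_target", 0.05),
        nPerm = getp("n_perm", 10),
        umrLmrCpgThreshold = getp("umr_lmr_cpg_threshold", 30),
        regionSizeFilterBp = getp("region_size_filter_bp", 500),
        promoterUpstream = getp("promoter_upstream", 1000),
        promoterDownstream = getp("promoter_downstream", 200),
        minCov = getp("min_cov", 5),
        overlapRule = getp("overlap_rule", "majority"),
        pmdEnabled = getp("pmd_enabled", FALSE),
        pmdMinLenBp = getp("pmd_min_len_bp", 10000),
        rngSeed = raw$seed)
    d <- raw$design
    if (!is.null(d)) {
        bad <- setdiff(names(d), DESIGN_KEYS)
        if (length(bad))
            stop("unknown design key(s): ", paste(bad, collapse = ", "))
    }
    getd <- function(key, default) if (is.null(d[[key]])) default
                                   else d[[key]]
    design <- simDesign(
        chromLengths = unlist(getd("chrom_lengths", list(chr1 = 2e6))),
        bgSpacing = getd("bg_spacing", 100),
        islandSpacing = getd("island_spacing", 10),
        stateMeans = unlist(getd("state_means",
            list(FMR = 0.85, UMR = 0.05, LMR = 0.30, PMD = 0.50))),
        stateConcs = unlist(getd("state_concs",
            list(FMR = 20, UMR = 20, LMR = 20, PMD = 4))),
        coverageLambda = getd("coverage_lambda", 20),
        rho = getd("rho", 0.05),
        nPhotoreceptorGenes = getd("n_photoreceptor_genes", 12),
        otherSets = unlist(getd("other_sets",
                                list(non_photoreceptor = 40))),
        nExtraUmr = getd("n_extra_umr", 10),
        nExtraLmr = getd("n_extra_lmr", 20),
        nPmd = getd("n_pmd", 0),
        geneSlotLenRange = unlist(getd("gene_slot_len_range",
                                       c(2000, 5000))),
        umrLenRange = unlist(getd("umr_len_range", c(1000, 5000))),
        lmrLenRange = unlist(getd("lmr_len_range", c(300, 1000))),
        pmdLenRange = unlist(getd("pmd_len_range", c(50000, 200000))))
    list(cfg = cfg, design = design, seed = as.integer(raw$seed),
         raw = raw)
}

configSnapshot <- function(cfg) {
    list(k_classes = cfg@kClasses,
         min_cpg_per_segment = cfg@minCpgPerSegment,
         cp_penalty = cfg@cpPenalty,
         smooth_window = cfg@smoothWindow,
         m_grid = cfg@mGrid, n_grid = cfg@nGrid,
         fdr_target = cfg@fdrTarget, n_perm = cfg@nPerm,
         umr_lmr_cpg_threshold = cfg@umrLmrCpgThreshold,
         region_size_filter_bp = cfg@regionSizeFilterBp,
         promoter_upstream = cfg@promoterUpstream,
         promoter_downstream = cfg@promoterDownstream,
         min_cov = cfg@minCov, overlap_rule = cfg@overlapRule,
         pmd_enabled = cfg@pmdEnabled, pmd_min_len_bp = cfg@pmdMinLenBp,
         rng_seed = cfg@rngSeed)
}

stageOut <- function(manifest, stage, files, rows) {
    manifest$stages[[stage]] <- list(outputs = files, rows = rows)
    manifest
}

#' Run the full methylome-state pipeline
#'
#' Executes simulate, segment, regions, optionally pmd, classify and
#' aggregate in order, writing plain-text outputs and a YAML run manifest
#' to \code{outDir}. Every configuration value actually used is logged and
#' recorded in the manifest; re-running with the same config reproduces
#' identical outputs for the deterministic stages.
#'
#' @param configPath YAML configuration (see \code{\link{validateConfig}}).
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.yaml}).
#' @export
runPipeline <- function(configPath, outDir = "methylstates_run",
                        quiet = FALSE) {
    vc <- validateConfig(configPath)
    cfg <- vc$cfg; design <- vc$design; seed <- vc$seed
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message(...)
    snap <- configSnapshot(cfg)
    say("config: ", paste(names(snap), vapply(snap, function(v)
        paste(format(v), collapse = ","), ""), sep = "=",
        collapse = "; "))
    manifest <- list(
        tool = "methylStates",
        version = as.character(utils::packageVersion("methylStates")),
        seed = seed,
        config = snap,
        inputs = list(config = list(
            path = normalizePath(configPath),
            md5 = unname(tools::md5sum(configPath)))),
        stages = list())
    fp <- function(...) file.path(outDir, ...)

    say("stage simulate")
    expmt <- simulateExperiment(design, deriveSeed(seed, "simulate"))
    files <- character(0); rows <- integer(0)
    for (nm in names(expmt$samples)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", nm)
        f <- fp(paste0(safe, ".cytosine_report.tsv"))
        writeCytosineReport(expmt$samples[[nm]], f)
        files <- c(files, f); rows <- c(rows, nSites(expmt$samples[[nm]]))
        ft <- fp(paste0(safe, ".truth_regions.tsv"))
        writeTruthRegionsTsv(expmt$truth[[nm]], ft)
        files <- c(files, ft)
        rows <- c(rows, length(truthRegions(expmt$truth[[nm]])))
    }
    writeGtf(expmt$geneModels, fp("genes.gtf"))
    writeGeneSets(expmt$geneSets, fp("gene_sets.tsv"))
    files <- c(files, fp("genes.gtf"), fp("gene_sets.tsv"))
    rows <- c(rows, length(exons(expmt$geneModels)),
              sum(lengths(expmt$geneSets)))
    manifest <- stageOut(manifest, "simulate", files, rows)

    say("stage segment")
    methylomes <- lapply(expmt$samples, filterCoverage, minCov = cfg@minCov)
    segSets <- lapply(methylomes, segmentMethylome, cfg = cfg)
    files <- character(0); rows <- integer(0)
    for (nm in names(segSets)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", nm)
        f <- fp(paste0(safe, ".segments.bed"))
        writeSegmentsBed(segSets[[nm]], f)
        ft <- fp(paste0(safe, ".segments.tsv"))
        writeCallsTsv(segmentMeanTable(segSets[[nm]]), ft)
        files <- c(files, f, ft)
        rows <- c(rows, length(segments(segSets[[nm]])),
                  length(segments(segSets[[nm]])))
    }
    manifest <- stageOut(manifest, "segment", files, rows)

    say("stage regions")
    files <- character(0); rows <- integer(0)
    regionSets <- list()
    for (nm in names(methylomes)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", nm)
        fdrRes <- calibrateFdr(methylomes[[nm]], cfg,
                               seed = deriveSeed(seed, paste0("fdr_", nm)))
        say("  ", nm, ": selected m*=", fdrRes@mStar, " n*=", fdrRes@nStar)
        regionSets[[nm]] <- callUmrLmr(methylomes[[nm]], fdrRes, cfg)
        f <- fp(paste0(safe, ".regions.bed"))
        writeRegionsBed(regionSets[[nm]], f)
        fg <- fp(paste0(safe, ".fdr_grid.tsv"))
        writeCallsTsv(fdrGrid(fdrRes), fg)
        files <- c(files, f, fg)
        rows <- c(rows, length(regions(regionSets[[nm]])),
                  nrow(fdrGrid(fdrRes)))
    }
    manifest <- stageOut(manifest, "regions", files, rows)

    if (cfg@pmdEnabled) {
        say("stage pmd")
        files <- character(0); rows <- integer(0)
        for (nm in names(methylomes)) {
            safe <- gsub("[^A-Za-z0-9]+", "_", nm)
            pmds <- callPmds(methylomes[[nm]],
                             minLenBp = cfg@pmdMinLenBp)
            f <- fp(paste0(safe, ".pmds.bed"))
            writeRegionsBed(pmds, f)
            files <- c(files, f); rows <- c(rows, length(regions(pmds)))
        }
        manifest <- stageOut(manifest, "pmd", files, rows)
    } else {
        manifest$stages[["pmd"]] <- list(outputs = list(),
                                         rows = integer(0),
                                         skipped = TRUE)
    }

    say("stage classify")
    promoters <- extractPromoters(expmt$geneModels, cfg@promoterUpstream,
                                  cfg@promoterDownstream,
                                  chromLengths = design@chromLengths)
    files <- character(0); rows <- integer(0)
    geneCallsList <- list()
    for (nm in names(methylomes)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", nm)
        pc <- callPromoters(promoters, segSets[[nm]], regionSets[[nm]],
                            methylomes[[nm]], cfg)
        gc <- selectRepresentative(pc, minSpan = cfg@regionSizeFilterBp)
        geneCallsList[[nm]] <- gc
        f <- fp(paste0(safe, ".promoter_calls.tsv"))
        writeCallsTsv(pc, f)
        fg <- fp(paste0(safe, ".gene_calls.tsv"))
        writeCallsTsv(gc, fg)
        files <- c(files, f, fg); rows <- c(rows, nrow(pc), nrow(gc))
    }
    manifest <- stageOut(manifest, "classify", files, rows)

    say("stage aggregate")
    pctRows <- list()
    for (nm in names(geneCallsList))
        for (setName in names(expmt$geneSets))
            pctRows[[length(pctRows) + 1L]] <- data.frame(
                sample = nm, geneSet = setName,
                pctHypermethylated = round(geneSetPercentage(
                    geneCallsList[[nm]], expmt$geneSets[[setName]]), 1))
    pct <- do.call(rbind, pctRows)
    writeCallsTsv(pct, fp("gene_set_percentages.tsv"))
    hm <- buildHeatmapMatrix(geneCallsList,
                             unlist(expmt$geneSets, use.names = FALSE))
    hmDf <- data.frame(geneId = rownames(hm), round(hm, 1),
                       check.names = FALSE)
    writeCallsTsv(hmDf, fp("heatmap_matrix.tsv"))
    manifest <- stageOut(manifest, "aggregate",
                         c(fp("gene_set_percentages.tsv"),
                           fp("heatmap_matrix.tsv")),
                         c(nrow(pct), nrow(hmDf)))

    yaml::write_yaml(manifest, fp("manifest.yaml"))
    say("done; manifest written to ", fp("manifest.yaml"))
    invisible(manifest)
}
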