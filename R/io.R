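#' Read a Bismark-style per-cytosine report
#'
#' Expects the genome-wide cytosine report layout: chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide (tab-separated). Only CpG-context rows are retained
#' (context \code{"CpG"} or \code{"CG"}); the symmetric counts of the two
#' strands of a CpG are merged onto the forward-strand cytosine by summing;
#' sites below \code{minCov} total reads are dropped.
#'
#' @param path file path.
#' @param minCov minimum merged read coverage to keep a site (default 5).
#' @param sampleId sample name; defaults to the file base name.
#' @return A \linkS4class{Methylome}.
#' @export
readCytosineReport <- function(path, minCov = 5, sampleId = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    nf <- utils::count.fields(path, sep = "\t", quote = "",
                              comment.char = "")
    if (is.null(nf) || length(nf) == 0L)
        stop("empty cytosine report: ", path)
    bad <- which(nf != 7L)
    if (length(bad))
        stop("malformed cytosine-report row at line ", bad[1L],
             " (expected 7 tab-separated fields, found ", nf[bad[1L]], ")")
    d <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = c("character", "integer", "character",
                                          "integer", "integer", "character",
                                          "character"))
    names(d) <- c("chrom", "pos", "strand", "meth", "unmeth", "context",
                  "tri")
    if (anyNA(d$pos) || anyNA(d$meth) || anyNA(d$unmeth))
        stop("malformed cytosine-report row at line ",
             which(is.na(d$pos) | is.na(d$meth) | is.na(d$unmeth))[1L])
    if (any(d$meth < 0L) || any(d$unmeth < 0L))
        stop("negative counts in cytosine report")
    d <- d[d$context %in% c("CpG", "CG"), , drop = FALSE]
    if (!all(d$strand %in% c("+", "-")))
        stop("cytosine-report strand must be '+' or '-'")
    if (anyDuplicated(paste(d$chrom, d$pos, d$strand)))
        stop("duplicate (chrom, pos, strand) sites in cytosine report")
    # reverse-strand G of a CpG sits one base right of the forward C
    fwdPos <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
    key <- paste(d$chrom, fwdPos)
    meth <- rowsum(d$meth, key)
    total <- rowsum(d$meth + d$unmeth, key)
    ord <- rownames(meth)
    parts <- matrix(unlist(strsplit(ord, " ", fixed = TRUE)),
                    ncol = 2, byrow = TRUE)
    keep <- total[, 1] >= minCov
    g <- GRanges(parts[keep, 1],
                 IRanges(as.integer(parts[keep, 2]), width = 1L),
                 countMeth = as.integer(meth[keep, 1]),
                 countTotal = as.integer(total[keep, 1]))
    Methylome(sampleId, g)
}

#' Read a Bismark coverage (.cov) file
#'
#' Layout: chromosome, 1-based start, 1-based end, methylation percent,
#' methylated count, unmethylated count. The percent column is recomputed
#' from the counts; a discrepancy above 0.5 percentage points triggers a
#' warning. Zero-coverage rows are dropped.
#'
#' @inheritParams readCytosineReport
#' @return A \linkS4class{Methylome}.
#' @export
readCoverageFile <- function(path, minCov = 5, sampleId = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    nf <- utils::count.fields(path, sep = "\t", quote = "",
                              comment.char = "")
    if (is.null(nf) || length(nf) == 0L)
        stop("empty coverage file: ", path)
    bad <- which(nf != 6L)
    if (length(bad))
        stop("malformed coverage row at line ", bad[1L],
             " (expected 6 tab-separated fields, found ", nf[bad[1L]], ")")
    d <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
    names(d) <- c("chrom", "start", "end", "pct", "meth", "unmeth")
    if (any(d$meth < 0L) || any(d$unmeth < 0L))
        stop("negative counts in coverage file")
    if (anyDuplicated(paste(d$chrom, d$start)))
        stop("duplicate sites in coverage file")
    total <- d$meth + d$unmeth
    nz <- total > 0L
    recomputed <- 100 * d$meth[nz] / total[nz]
    if (any(abs(recomputed - d$pct[nz]) > 0.5))
        warning("percent column disagrees with counts by > 0.5 points at ",
                sum(abs(recomputed - d$pct[nz]) > 0.5), " site(s)")
    keep <- nz & total >= minCov
    g <- GRanges(d$chrom[keep], IRanges(d$start[keep], width = 1L),
                 countMeth = d$meth[keep],
                 countTotal = total[keep])
    Methylome(sampleId, g)
}

#' Write a Methylome as a cytosine report or coverage file
#'
#' Counts and 1-based coordinates round-trip bit-exactly through
#' \code{readCytosineReport} / \code{readCoverageFile} (at
#' \code{minCov = 1}). The cytosine report is written forward-strand only
#' (strand-merged counts).
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeCytosineReport <- function(methylome, path) {
    s <- methSites(methylome)
    d <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                    strand = "+", meth = mcols(s)$countMeth,
                    unmeth = mcols(s)$countTotal - mcols(s)$countMeth,
                    context = "CpG", tri = "CGN")
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeCytosineReport
#' @export
writeCoverageFile <- function(methylome, path) {
    s <- methSites(methylome)
    pct <- 100 * mcols(s)$countMeth / mcols(s)$countTotal
    d <- data.frame(chrom = as.character(seqnames(s)), start = start(s),
                    end = start(s),
                    pct = formatC(pct, digits = 6, format = "f"),
                    meth = mcols(s)$countMeth,
                    unmeth = mcols(s)$countTotal - mcols(s)$countMeth)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene models from GTF/GFF or BED12
#'
#' GTF/GFF files are parsed for \code{exon} features grouped by
#' \code{transcript_id} (with \code{gene_id}); BED12 blocks become exons,
#' with the \code{name} field serving as both transcript and gene id. The
#' transcription start site of each transcript is the 5'-most exon boundary
#' in transcript orientation and the first exon is the 5'-most exon.
#'
#' @param path GTF/GFF (\code{.gtf}, \code{.gff}, \code{.gff2},
#'   \code{.gff3}) or BED12 (\code{.bed}) file.
#' @return A \linkS4class{GeneModels}.
#' @export
readGeneModels <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "bed") {
        b <- rtracklayer::import(path, format = "bed")
        if (!length(b)) stop("no records in ", path)
        blocks <- b$blocks
        if (is.null(blocks)) {  # BED6: one exon per record
            ex <- granges(b)
            mcols(ex)$geneId <- b$name
            mcols(ex)$transcriptId <- b$name
        } else {
            ex <- unlist(rtracklayer::blocks(b))
            ids <- rep(b$name, lengths(blocks))
            mcols(ex) <- NULL
            mcols(ex)$geneId <- ids
            mcols(ex)$transcriptId <- ids
        }
    } else {
        g <- rtracklayer::import(path)
        g <- g[tolower(as.character(g$type)) == "exon"]
        if (!length(g)) stop("no exon features in ", path)
        if (is.null(g$transcript_id) || is.null(g$gene_id))
            stop("exon features need gene_id and transcript_id attributes")
        ex <- granges(g)
        mcols(ex)$geneId <- g$gene_id
        mcols(ex)$transcriptId <- g$transcript_id
    }
    ex <- GenomicRanges::sort(ex, ignore.strand = TRUE)
    byTx <- split(seq_along(ex), mcols(ex)$transcriptId)
    for (i in byTx) {
        if (length(i) > 1) {
            o <- order(start(ex)[i])
            if (any(start(ex)[i][o][-1] <= end(ex)[i][o][-length(i)]))
                stop("overlapping exons within transcript ",
                     mcols(ex)$transcriptId[i[1]])
        }
    }
    GeneModels(ex)
}

#' Per-transcript summary of gene models
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @return data.frame with one row per transcript: \code{geneId},
#'   \code{transcriptId}, \code{chrom}, \code{strand}, \code{tss} (1-based
#'   position of the first transcribed base), and the first exon's
#'   \code{firstExonStart}/\code{firstExonEnd} (1-based closed).
#' @export
transcriptTable <- function(geneModels) {
    ex <- exons(geneModels)
    tx <- mcols(ex)$transcriptId
    idx <- split(seq_along(ex), tx)
    rows <- lapply(idx, function(i) {
        str <- as.character(strand(ex[i[1]]))
        st <- start(ex)[i]; en <- end(ex)[i]
        if (str == "+") {
            j <- which.min(st)
            data.frame(geneId = mcols(ex)$geneId[i[1]],
                       transcriptId = tx[i[1]],
                       chrom = as.character(seqnames(ex[i[1]])),
                       strand = str, tss = st[j],
                       firstExonStart = st[j], firstExonEnd = en[j])
        } else {
            j <- which.max(en)
            data.frame(geneId = mcols(ex)$geneId[i[1]],
                       transcriptId = tx[i[1]],
                       chrom = as.character(seqnames(ex[i[1]])),
                       strand = str, tss = en[j],
                       firstExonStart = st[j], firstExonEnd = en[j])
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$chrom, out$tss), , drop = FALSE]
}

#' Read phenotype gene sets from TSV
#'
#' Two tab-separated columns: set name and gene id (a header line
#' \code{set_name<TAB>gene_id} is tolerated). Duplicated genes within a set
#' are dropped with a warning; sets may share genes.
#'
#' @param path TSV file path.
#' @return Named list of character vectors of gene ids.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty gene-set file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("gene-set rows must have exactly 2 tab-separated fields ",
             "(line ", which(lengths(parts) != 2L)[1L], ")")
    d <- data.frame(set = vapply(parts, `[`, "", 1L),
                    gene = vapply(parts, `[`, "", 2L))
    if (identical(tolower(d$set[1]), "set_name"))
        d <- d[-1, , drop = FALSE]
    if (!nrow(d)) stop("no gene-set entries in ", path)
    sets <- split(d$gene, d$set)
    sets <- sets[unique(d$set)]   # preserve file order of sets
    lapply(stats::setNames(names(sets), names(sets)), function(nm) {
        g <- sets[[nm]]
        if (anyDuplicated(g)) {
            warning("duplicated gene(s) in set '", nm, "' deduplicated")
            g <- unique(g)
        }
        g
    })
}

#' @rdname readGeneSets
#' @param geneSets named list of character vectors.
#' @param path output TSV path.
#' @export
writeGeneSets <- function(geneSets, path) {
    d <- data.frame(set = rep(names(geneSets), lengths(geneSets)),
                    gene = unlist(geneSets, use.names = FALSE))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

bedStart0 <- function(g) format(start(g) - 1L, scientific = FALSE,
                                trim = TRUE)
bedEnd <- function(g) format(end(g), scientific = FALSE, trim = TRUE)

#' Write BED / bedGraph / TSV outputs
#'
#' BED and bedGraph use 0-based half-open coordinates. Segment classes are
#' encoded in the BED name field as \code{class_3}; region types as
#' \code{UMR}/\code{LMR}/\code{PMD}. The BED score column carries
#' \code{round(1000 * meanMeth)}. Every file begins with a track line, so an
#' empty set yields a header-only file.
#'
#' @param x a \linkS4class{SegmentSet}, \linkS4class{RegionSet},
#'   \linkS4class{Methylome} or data.frame as appropriate.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeSegmentsBed <- function(x, path) {
    g <- segments(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines('track name="segments" description="methylome segmentation"',
               con)
    if (length(g)) {
        cls <- mcols(g)$segClass
        d <- paste(as.character(seqnames(g)), bedStart0(g), bedEnd(g),
                   ifelse(is.na(cls), "class_NA", paste0("class_", cls)),
                   round(1000 * mcols(g)$meanMeth), ".", sep = "\t")
        writeLines(d, con)
    }
    invisible(path)
}

#' @rdname writeSegmentsBed
#' @export
writeRegionsBed <- function(x, path) {
    g <- if (is(x, "RegionSet")) regions(x) else x
    con <- file(path, "w")
    on.exit(close(con))
    writeLines('track name="regions" description="UMR/LMR/PMD calls"', con)
    if (length(g)) {
        nm <- if ("regionType" %in% colnames(mcols(g))) mcols(g)$regionType
              else if ("trueState" %in% colnames(mcols(g)))
                  mcols(g)$trueState
              else "region"
        sc <- if ("meanMeth" %in% colnames(mcols(g)))
                  round(1000 * mcols(g)$meanMeth)
              else if ("trueMean" %in% colnames(mcols(g)))
                  round(1000 * mcols(g)$trueMean)
              else 0
        writeLines(paste(as.character(seqnames(g)), bedStart0(g), bedEnd(g),
                         nm, sc, ".", sep = "\t"), con)
    }
    invisible(path)
}

#' @rdname writeSegmentsBed
#' @export
writeBedgraph <- function(x, path) {
    s <- methSites(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf('track type=bedGraph name="%s"', sampleId(x)), con)
    if (length(s)) {
        fr <- formatC(methFraction(x), digits = 6, format = "f")
        writeLines(paste(as.character(seqnames(s)), bedStart0(s), bedEnd(s),
                         fr, sep = "\t"), con)
    }
    invisible(path)
}

#' @rdname writeSegmentsBed
#' @export
writeCallsTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Write gene models as GTF
#'
#' One \code{exon} feature per exon with \code{gene_id} and
#' \code{transcript_id} attributes; readable back with
#' \code{\link{readGeneModels}}.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGtf <- function(geneModels, path) {
    ex <- exons(geneModels)
    attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                    mcols(ex)$geneId, mcols(ex)$transcriptId)
    d <- paste(as.character(seqnames(ex)), "methylStates", "exon",
               format(start(ex), scientific = FALSE, trim = TRUE),
               format(end(ex), scientific = FALSE, trim = TRUE),
               ".", as.character(strand(ex)), ".", attr, sep = "\t")
    writeLines(d, path)
    invisible(path)
}

#' Write and re-read simulator truth regions
#'
#' The TSV stores the planted tiling exactly (chromosome, 0-based half-open
#' interval, state, true mean at full precision) so that planted regions
#' round-trip without loss.
#'
#' @param truth a \linkS4class{TruthTable} (for writing).
#' @param path TSV path.
#' @return \code{readTruthRegionsTsv}: GRanges with \code{trueState} and
#'   \code{trueMean} metadata columns.
#' @export
writeTruthRegionsTsv <- function(truth, path) {
    g <- truthRegions(truth)
    d <- data.frame(chrom = as.character(seqnames(g)),
                    start0 = start(g) - 1L, end = end(g),
                    state = mcols(g)$trueState,
                    trueMean = formatC(mcols(g)$trueMean, digits = 10,
                                       format = "g"))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeTruthRegionsTsv
#' @export
readTruthRegionsTsv <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric"))
    GRanges(d$chrom, IRanges(d$start0 + 1L, d$end),
            trueState = d$state, trueMean = d$trueMean)
}
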