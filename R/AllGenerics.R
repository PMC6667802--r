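#' Accessors for methylStates objects
#'
#' @param x a methylStates object.
#' @return \code{sampleId}: the sample name; \code{methSites},
#'   \code{segments}, \code{regions}, \code{exons}: the underlying GRanges;
#'   \code{methFraction}: per-site methylation fractions in site order.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("methSites", function(x) standardGeneric("methSites"))
#' @rdname accessors
#' @export
setGeneric("methFraction", function(x) standardGeneric("methFraction"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname accessors
#' @export
setMethod("sampleId", "Methylome", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("methSites", "Methylome", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("methFraction", "Methylome", function(x) {
    mc <- mcols(x@sites)
    as.numeric(mc$countMeth) / as.numeric(mc$countTotal)
})
#' @rdname accessors
#' @export
setMethod("segments", "SegmentSet", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("exons", "GeneModels", function(x) x@exons)

#' @rdname accessors
#' @param ... unused.
#' @export
setGeneric("nSites", function(x, ...) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setMethod("nSites", "Methylome", function(x, ...) length(x@sites))

#' FDR grid accessors
#'
#' @param x an \linkS4class{FdrGridResult}.
#' @return \code{fdrGrid}: the grid data.frame; \code{selectedCutoffs}: a
#'   named list with elements \code{m} and \code{n}.
#' @export
fdrGrid <- function(x) x@grid

#' @rdname fdrGrid
#' @export
selectedCutoffs <- function(x) list(m = x@mStar, n = x@nStar)

#' Truth-table accessors
#'
#' @param x a \linkS4class{TruthTable}.
#' @return \code{truthRegions}: planted-state tiling GRanges;
#'   \code{truthSiteProbs}: per-CpG true methylation probabilities;
#'   \code{intendedCalls}: planted per-gene hypermethylation verdicts.
#' @export
truthRegions <- function(x) x@regions

#' @rdname truthRegions
#' @export
truthSiteProbs <- function(x) x@siteProbs

#' @rdname truthRegions
#' @export
intendedCalls <- function(x) x@intendedCalls
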