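# Constructors, accessors and show methods for the core classes.

# internal: build a GRanges from 0-based half-open bp coordinates
.bpGRanges <- function(chrom, start, end, cloneId = NULL) {
    gr <- GRanges(chrom, IRanges(start = start + 1L, end = end))
    if (!is.null(cloneId)) mcols(gr)$cloneId <- cloneId
    gr
}

# internal: 0-based half-open bp bounds of a GRanges
.bpBounds <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr))
}

#' Construct an AcghProfile
#'
#' @param sampleName sample identifier.
#' @param cloneId character vector of clone identifiers.
#' @param chrom chromosome per clone.
#' @param start,end 0-based half-open clone coordinates in bp.
#' @param replicates numeric matrix of replicate log2 ratios
#'   (clones x replicate spots).
#' @param replicateSD per-clone replicate standard deviation; computed from
#'   `replicates` when `NULL`.
#' @param snr per-clone signal-to-noise ratio.
#' @return An [AcghProfile-class] object with combined log2 ratios set to the
#'   arithmetic mean of the replicate spots and no clone flagged missing.
#' @export
AcghProfile <- function(sampleName, cloneId, chrom, start, end,
                        replicates, replicateSD = NULL, snr) {
    replicates <- as.matrix(replicates)
    o <- order(chrom, start)
    replicates <- replicates[o, , drop = FALSE]
    if (is.null(replicateSD))
        replicateSD <- apply(replicates, 1L, stats::sd)
    else
        replicateSD <- replicateSD[o]
    new("AcghProfile",
        sampleName  = as.character(sampleName),
        clones      = .bpGRanges(chrom[o], start[o], end[o], cloneId[o]),
        replicates  = replicates,
        replicateSD = replicateSD,
        snr         = snr[o],
        log2Ratio   = rowMeans(replicates),
        missing     = rep(FALSE, nrow(replicates)),
        qcReport    = list())
}

#' Construct an ExpressionPanel
#'
#' @param exprs probes x samples numeric matrix.
#' @param probeMap data.frame with `probeId`, `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param cohorts cohort label per sample column.
#' @param scale `"log10"` (default), `"log2"` or `"linear"`.
#' @return An [ExpressionPanel-class].
#' @export
ExpressionPanel <- function(exprs, probeMap, cohorts, scale = "log10") {
    exprs <- as.matrix(exprs)
    new("ExpressionPanel", exprs = exprs, probeMap = probeMap,
        cohorts = as.factor(cohorts), scale = scale)
}

#' @rdname AcghProfile-class
#' @param object,x an `AcghProfile`.
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))
#' @rdname AcghProfile-class
#' @export
setMethod("sampleName", "AcghProfile", function(x) x@sampleName)
#' @rdname SegmentedProfile-class
#' @export
setMethod("sampleName", "SegmentedProfile", function(x) x@sampleName)

#' @rdname AcghProfile-class
#' @export
setGeneric("cloneRanges", function(x) standardGeneric("cloneRanges"))
#' @rdname AcghProfile-class
#' @export
setMethod("cloneRanges", "AcghProfile", function(x) x@clones)
#' @rdname SegmentedProfile-class
#' @export
setMethod("cloneRanges", "SegmentedProfile", function(x) x@clones)
#' @rdname StateMatrix-class
#' @export
setMethod("cloneRanges", "StateMatrix", function(x) x@clones)

#' @rdname AcghProfile-class
#' @export
setGeneric("log2Ratios", function(x) standardGeneric("log2Ratios"))
#' @rdname AcghProfile-class
#' @export
setMethod("log2Ratios", "AcghProfile", function(x) x@log2Ratio)

#' @rdname AcghProfile-class
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))
#' @rdname AcghProfile-class
#' @export
setMethod("isMissing", "AcghProfile", function(x) x@missing)
#' @rdname SegmentedProfile-class
#' @export
setMethod("isMissing", "SegmentedProfile", function(x) x@missing)

#' @rdname AcghProfile-class
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))
#' @rdname AcghProfile-class
#' @export
setMethod("qcReport", "AcghProfile", function(x) x@qcReport)

#' @rdname SegmentedProfile-class
#' @param x a `SegmentedProfile`.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname SegmentedProfile-class
#' @export
setMethod("segmentTable", "SegmentedProfile", function(x) x@segments)

#' @rdname StateMatrix-class
#' @param x a `StateMatrix`.
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname StateMatrix-class
#' @export
setMethod("states", "StateMatrix", function(x) x@states)

#' @rdname StateMatrix-class
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))
#' @rdname StateMatrix-class
#' @export
setMethod("cohorts", "StateMatrix", function(x) x@cohorts)
#' @rdname ExpressionPanel-class
#' @export
setMethod("cohorts", "ExpressionPanel", function(x) x@cohorts)

#' @rdname ExpressionPanel-class
#' @param x an `ExpressionPanel`.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname ExpressionPanel-class
#' @export
setMethod("exprValues", "ExpressionPanel", function(x) x@exprs)

#' @rdname ExpressionPanel-class
#' @export
setGeneric("probeMap", function(x) standardGeneric("probeMap"))
#' @rdname ExpressionPanel-class
#' @export
setMethod("probeMap", "ExpressionPanel", function(x) x@probeMap)

#' @rdname ExpressionPanel-class
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @rdname ExpressionPanel-class
#' @export
setMethod("exprScale", "ExpressionPanel", function(x) x@scale)

setMethod("show", "AcghProfile", function(object) {
    n <- length(object@clones)
    cat("AcghProfile '", object@sampleName, "': ", n, " clones, ",
        sum(object@missing), " missing (QC), ",
        ncol(object@replicates), " replicate spots\n", sep = "")
})

setMethod("show", "SegmentedProfile", function(object) {
    cat("SegmentedProfile '", object@sampleName, "': ",
        nrow(object@segments), " segments over ",
        length(object@clones), " clones (",
        sum(object@segments$state == 1L), " gain / ",
        sum(object@segments$state == -1L), " loss)\n", sep = "")
})

setMethod("show", "StateMatrix", function(object) {
    cat("StateMatrix: ", nrow(object@states), " clones x ",
        ncol(object@states), " samples; cohorts: ",
        paste(sprintf("%s=%d", levels(object@cohorts),
                      tabulate(object@cohorts)), collapse = ", "),
        "; ", sum(is.na(object@states)), " missing entries\n", sep = "")
})

setMethod("show", "ExpressionPanel", function(object) {
    cat("ExpressionPanel: ", nrow(object@exprs), " probes x ",
        ncol(object@exprs), " samples (", object@scale, " scale); cohorts: ",
        paste(sprintf("%s=%d", levels(object@cohorts),
                      tabulate(object@cohorts)), collapse = ", "), "\n",
        sep = "")
})
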