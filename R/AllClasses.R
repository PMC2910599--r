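#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect granges mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @useDynLib lineamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' AcghProfile: one aCGH hybridization
#'
#' Holds the ordered clone (array element) measurements for a single sample:
#' clone coordinates as a [GenomicRanges::GRanges], the replicate spot log2
#' ratios, the replicate standard deviation and signal-to-noise ratio per
#' clone, the replicate-combined log2 ratio, and a missing flag set by
#' quality control.
#'
#' @slot sampleName single character sample identifier.
#' @slot clones `GRanges` of clone positions (0-based half-open converted to
#'   1-based `IRanges` internally), with a `cloneId` metadata column; sorted
#'   by (chromosome, start).
#' @slot replicates numeric matrix, clones x replicate spots, of log2 ratios.
#' @slot replicateSD numeric, per-clone standard deviation across replicates.
#' @slot snr numeric, per-clone signal-to-noise ratio.
#' @slot log2Ratio numeric, per-clone combined log2 ratio (mean of passing
#'   replicates); `NA` where missing.
#' @slot missing logical, `TRUE` for clones removed by QC.
#' @slot qcReport list with counts of removed clones (filled by [qcFilter()]).
#'
#' @seealso [AcghProfile()], [qcFilter()], [segmentProfile()]
#' @export
setClass("AcghProfile",
    representation(
        sampleName  = "character",
        clones      = "GRanges",
        replicates  = "matrix",
        replicateSD = "numeric",
        snr         = "numeric",
        log2Ratio   = "numeric",
        missing     = "logical",
        qcReport    = "list"
    )
)

setValidity("AcghProfile", function(object) {
    n <- length(object@clones)
    msg <- character(0)
    if (length(object@sampleName) != 1L)
        msg <- c(msg, "sampleName must be a single string")
    if (is.null(object@clones$cloneId))
        msg <- c(msg, "clones must carry a 'cloneId' metadata column")
    if (anyDuplicated(object@clones$cloneId))
        msg <- c(msg, "duplicate clone ids")
    if (nrow(object@replicates) != n)
        msg <- c(msg, "replicate matrix rows must match number of clones")
    for (sl in c("replicateSD", "snr", "log2Ratio", "missing"))
        if (length(slot(object, sl)) != n)
            msg <- c(msg, sprintf("slot '%s' must have one entry per clone", sl))
    if (n > 1) {
        o <- order(as.integer(seqnames(object@clones)), start(object@clones))
        if (!identical(o, seq_len(n)))
            msg <- c(msg, "clones must be sorted by (chrom, start)")
    }
    if (any(!object@missing & is.na(object@log2Ratio)))
        msg <- c(msg, "combined log2 must be defined for non-missing clones")
    if (length(msg)) msg else TRUE
})

#' SegmentedProfile: piecewise-constant fit of one aCGH profile
#'
#' @slot sampleName sample identifier.
#' @slot clones `GRanges` of the clone grid (copied from the input profile).
#' @slot segments `data.frame` with columns `startIndex`, `endIndex` (1-based
#'   clone indices, contiguous and non-overlapping, covering the full grid),
#'   `mean` (segment mean log2) and `state` (-1, 0, +1).
#' @slot missing logical per clone, carried over from QC.
#'
#' @seealso [segmentProfile()], [callStates()]
#' @export
setClass("SegmentedProfile",
    representation(
        sampleName = "character",
        clones     = "GRanges",
        segments   = "data.frame",
        missing    = "logical"
    )
)

setValidity("SegmentedProfile", function(object) {
    seg <- object@segments
    n <- length(object@clones)
    msg <- character(0)
    need <- c("startIndex", "endIndex", "mean", "state")
    if (!all(need %in% names(seg)))
        return("segments must have columns startIndex, endIndex, mean, state")
    if (nrow(seg)) {
        if (any(seg$startIndex < 1L) || any(seg$endIndex > n) ||
            any(seg$startIndex > seg$endIndex))
            msg <- c(msg, "segment indices out of range")
        if (nrow(seg) > 1 &&
            !all(seg$startIndex[-1] > seg$endIndex[-nrow(seg)]))
            msg <- c(msg, "segments must be ordered and non-overlapping")
        if (!all(seg$state %in% c(-1L, 0L, 1L)))
            msg <- c(msg, "segment states must be -1, 0 or +1")
    }
    if (length(msg)) msg else TRUE
})

#' StateMatrix: copy-number states for a clone grid across samples
#'
#' Clones x samples matrix with entries in \{-1, 0, +1\} (NA = missing), a
#' cohort label per sample, and an `observed` mask distinguishing measured
#' from imputed entries (imputation only ever draws donors from originally
#' observed entries, which makes it idempotent).
#'
#' @slot states integer matrix, clones x samples, entries -1/0/1/NA.
#' @slot clones `GRanges` of the common clone grid.
#' @slot cohorts factor of cohort labels, one per sample (column).
#' @slot observed logical matrix, same dim as `states`; `TRUE` where the
#'   state was measured rather than imputed.
#'
#' @seealso [buildStateMatrix()], [imputeMissingStates()], [compareCohorts()]
#' @export
setClass("StateMatrix",
    representation(
        states   = "matrix",
        clones   = "GRanges",
        cohorts  = "factor",
        observed = "matrix"
    )
)

setValidity("StateMatrix", function(object) {
    msg <- character(0)
    if (nrow(object@states) != length(object@clones))
        msg <- c(msg, "states must have one row per clone")
    if (ncol(object@states) != length(object@cohorts))
        msg <- c(msg, "cohorts must have one label per sample column")
    if (!identical(dim(object@states), dim(object@observed)))
        msg <- c(msg, "observed mask must match states dimensions")
    vals <- object@states[!is.na(object@states)]
    if (length(vals) && !all(vals %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "states must be -1, 0, +1 or NA")
    if (length(msg)) msg else TRUE
})

#' ExpressionPanel: probe-level expression with genomic annotation
#'
#' @slot exprs numeric matrix, probes x samples.
#' @slot probeMap `data.frame` with columns `probeId`, `gene`, `chrom`,
#'   `start`, `end` (0-based half-open gene interval), one row per probe.
#' @slot cohorts factor of cohort labels per sample.
#' @slot scale character, one of `"log10"`, `"log2"`, `"linear"`; the scale
#'   of the stored values (used when fold changes are computed).
#'
#' @seealso [ExpressionPanel()], [diffExpression()], [tumorVsNormal()]
#' @export
setClass("ExpressionPanel",
    representation(
        exprs    = "matrix",
        probeMap = "data.frame",
        cohorts  = "factor",
        scale    = "character"
    )
)

setValidity("ExpressionPanel", function(object) {
    msg <- character(0)
    need <- c("probeId", "gene", "chrom", "start", "end")
    if (!all(need %in% names(object@probeMap)))
        msg <- c(msg, "probeMap needs columns probeId, gene, chrom, start, end")
    else {
        if (nrow(object@probeMap) != nrow(object@exprs))
            msg <- c(msg, "probeMap must have one row per expression probe")
        if (anyDuplicated(object@probeMap$probeId))
            msg <- c(msg, "duplicate probe ids")
        bad <- object@probeMap$start >= object@probeMap$end
        if (any(bad)) msg <- c(msg, "probe intervals must satisfy start < end")
    }
    if (ncol(object@exprs) != length(object@cohorts))
        msg <- c(msg, "cohorts must have one label per sample column")
    if (!object@scale %in% c("log10", "log2", "linear"))
        msg <- c(msg, "scale must be 'log10', 'log2' or 'linear'")
    if (length(msg)) msg else TRUE
})
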