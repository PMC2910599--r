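#' Exact penalised least-squares segmentation of a numeric vector
#'
#' Dynamic programme minimising `SSE + penalty * (number of breakpoints)`,
#' with the breakpoint count capped at `maxBreakpoints`. The optimum is
#' exact; ties are resolved in favour of fewer breakpoints. This is the core
#' used by [segmentProfile()] and is exposed so the objective can be checked
#' against exhaustive search.
#'
#' @param x numeric vector (no NAs).
#' @param penalty non-negative penalty per breakpoint, in squared-log2 units.
#' @param maxBreakpoints hard cap on the number of breakpoints.
#' @return `data.frame` with one row per segment: `startIndex`, `endIndex`
#'   (1-based, inclusive), `mean`; attribute `"objective"` holds the achieved
#'   penalised objective.
#' @export
segmentLog2 <- function(x, penalty, maxBreakpoints) {
    stopifnot(is.numeric(x), length(x) >= 1L, !anyNA(x),
              penalty >= 0, maxBreakpoints >= 0)
    fit <- dp_segment_cpp(as.numeric(x), penalty, as.integer(maxBreakpoints))
    out <- data.frame(startIndex = fit$start, endIndex = fit$end,
                      mean = fit$mean)
    attr(out, "objective") <- fit$objective
    out
}

#' Segment an aCGH profile into piecewise-constant copy-number levels
#'
#' Fits an exact penalised least-squares segmentation to the combined log2
#' ratios of the non-missing clones, then assigns each segment a state by
#' comparing its mean to the gain/loss thresholds. The penalty is
#' `penaltyLambda` times a robust estimate of the per-clone noise variance
#' (squared MAD of first differences divided by two), so `penaltyLambda` is
#' a dimensionless smoothing knob; clones removed by QC carry no value but
#' are attached to the segment covering their position (a missing clone
#' between two fitted clones joins the left segment).
#'
#' @param profile an [AcghProfile-class] (QC-filtered or not).
#' @param penaltyLambda dimensionless per-breakpoint penalty (default 6.75).
#' @param maxBreakpoints cap on breakpoints per chromosome (default 100).
#' @param gainThreshold segment mean log2 above which a segment is a gain
#'   (default +0.2).
#' @param lossThreshold segment mean log2 below which a segment is a loss
#'   (default -0.2).
#' @return A [SegmentedProfile-class].
#' @export
segmentProfile <- function(profile, penaltyLambda = 6.75,
                           maxBreakpoints = 100,
                           gainThreshold = 0.2, lossThreshold = -0.2) {
    stopifnot(is(profile, "AcghProfile"),
              gainThreshold > 0, lossThreshold < 0, maxBreakpoints >= 0)
    if (!any(!profile@missing))
        stop("no non-missing clones to segment in sample '",
             profile@sampleName, "'")
    chrom <- as.character(seqnames(profile@clones))
    segList <- list()
    for (ch in unique(chrom)) {
        inChrom <- which(chrom == ch)
        keep <- inChrom[!profile@missing[inChrom]]
        if (!length(keep)) {
            warning("chromosome '", ch, "' has no usable clones in sample '",
                    profile@sampleName, "'; skipped")
            next
        }
        vals <- profile@log2Ratio[keep]
        # robust per-clone noise SD from successive differences
        sigma <- if (length(vals) > 1L)
            stats::mad(diff(vals)) / sqrt(2) else 0
        penalty <- penaltyLambda * max(sigma^2, 1e-12)
        fit <- segmentLog2(vals, penalty, maxBreakpoints)
        # map segment bounds from the non-missing subsequence back to the
        # full clone grid: leading missing clones join the first segment,
        # internal and trailing missing clones join the segment to their left
        startFull <- c(inChrom[1L], keep[fit$startIndex[-1L]])
        endFull   <- c(startFull[-1L] - 1L, inChrom[length(inChrom)])
        segList[[ch]] <- data.frame(startIndex = as.integer(startFull),
                                    endIndex = as.integer(endFull),
                                    mean = fit$mean)
    }
    seg <- do.call(rbind, c(segList, list(make.row.names = FALSE)))
    seg$state <- ifelse(seg$mean > gainThreshold, 1L,
                 ifelse(seg$mean < lossThreshold, -1L, 0L))
    new("SegmentedProfile",
        sampleName = profile@sampleName,
        clones     = profile@clones,
        segments   = seg,
        missing    = profile@missing)
}

#' Per-clone copy-number states of a segmented profile
#'
#' Each non-missing clone receives the state of its covering segment;
#' clones removed by QC are returned as `NA` and are to be imputed from
#' neighbours downstream (see [imputeMissingStates()]).
#'
#' @param seg a [SegmentedProfile-class].
#' @return integer vector of length equal to the clone count, entries in
#'   \{-1, 0, +1, NA\}.
#' @export
callStates <- function(seg) {
    stopifnot(is(seg, "SegmentedProfile"))
    st <- rep(NA_integer_, length(seg@clones))
    for (i in seq_len(nrow(seg@segments)))
        st[seg@segments$startIndex[i]:seg@segments$endIndex[i]] <-
            seg@segments$state[i]
    st[seg@missing] <- NA_integer_
    st
}
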