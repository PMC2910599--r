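#' Detect high-level amplifications in one profile
#'
#' Scans the combined log2 ratios (or, optionally, the per-clone segment
#' means) for maximal runs of consecutive non-missing clones on the same
#' chromosome whose value exceeds `threshold`. Runs shorter than
#' `minConsecutive` elements are rejected, and a run can never bridge a
#' missing clone. The conventional thresholds are 0.6 for tumors and 0.8
#' for carcinoma-in-situ lesions, where cell heterogeneity dilutes the
#' signal less predictably.
#'
#' @param profile an [AcghProfile-class].
#' @param threshold log2 ratio that must be strictly exceeded (default 0.6).
#' @param minConsecutive minimal run length in array elements (default 2).
#' @param segmented optional [SegmentedProfile-class]; when supplied the scan
#'   runs on per-clone segment means instead of raw combined ratios.
#' @return `data.frame` with one row per amplified interval: `chrom`,
#'   `start`, `end` (0-based half-open bp bounds of the first/last clone in
#'   the run), `startIndex`, `endIndex` (clone indices), `nClones`,
#'   `meanLog2`.
#' @export
detectAmplifications <- function(profile, threshold = 0.6,
                                 minConsecutive = 2, segmented = NULL) {
    stopifnot(is(profile, "AcghProfile"), threshold > 0, minConsecutive >= 2)
    vals <- profile@log2Ratio
    if (!is.null(segmented)) {
        stopifnot(is(segmented, "SegmentedProfile"))
        sg <- segmented@segments
        for (i in seq_len(nrow(sg)))
            vals[sg$startIndex[i]:sg$endIndex[i]] <- sg$mean[i]
        vals[profile@missing] <- NA_real_
    }
    chrom <- as.character(seqnames(profile@clones))
    qual  <- !is.na(vals) & vals > threshold
    # break runs at chromosome boundaries
    grp <- cumsum(c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                          qual[-1L] != qual[-length(qual)]))
    out <- list()
    for (g in unique(grp[qual])) {
        idx <- which(grp == g)
        if (length(idx) < minConsecutive) next
        out[[length(out) + 1L]] <- data.frame(
            chrom      = chrom[idx[1L]],
            start      = start(profile@clones)[idx[1L]] - 1L,
            end        = end(profile@clones)[idx[length(idx)]],
            startIndex = idx[1L],
            endIndex   = idx[length(idx)],
            nClones    = length(idx),
            meanLog2   = mean(vals[idx]))
    }
    if (!length(out))
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), startIndex = integer(0),
                          endIndex = integer(0), nClones = integer(0),
                          meanLog2 = numeric(0)))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group-level amplification score
#'
#' For a set of samples on a common clone grid, counts per clone how many
#' samples carry an amplified interval covering it, and the corresponding
#' fraction. This summarises per-case amplicon definitions across a group
#' to give the incidence of amplification along the arm.
#'
#' @param profiles list of [AcghProfile-class] objects on identical clone
#'   grids.
#' @param threshold,minConsecutive passed to [detectAmplifications()].
#' @param segmentedList optional list of matching [SegmentedProfile-class]
#'   objects (same order) to score segment means instead of raw ratios.
#' @return `data.frame` with one row per clone: `chrom`, `start`, `end`,
#'   `count`, `fraction`.
#' @export
amplificationScore <- function(profiles, threshold = 0.6, minConsecutive = 2,
                               segmentedList = NULL) {
    stopifnot(length(profiles) >= 1L)
    ref <- profiles[[1L]]@clones
    for (p in profiles[-1L])
        if (length(p@clones) != length(ref) ||
            !all(as.character(seqnames(p@clones)) ==
                 as.character(seqnames(ref))) ||
            !all(start(p@clones) == start(ref)) ||
            !all(end(p@clones) == end(ref)))
            stop("inconsistent clone grids across samples")
    count <- integer(length(ref))
    for (i in seq_along(profiles)) {
        seg <- if (is.null(segmentedList)) NULL else segmentedList[[i]]
        amp <- detectAmplifications(profiles[[i]], threshold, minConsecutive,
                                    segmented = seg)
        for (j in seq_len(nrow(amp)))
            count[amp$startIndex[j]:amp$endIndex[j]] <-
                count[amp$startIndex[j]:amp$endIndex[j]] + 1L
    }
    cbind(.bpBounds(ref),
          data.frame(count = count, fraction = count / length(profiles)))
}
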