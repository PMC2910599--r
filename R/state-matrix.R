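#' Build a StateMatrix from segmented profiles
#'
#' Stacks per-sample state calls (see [callStates()]) on a common clone grid
#' into a clones x samples matrix with cohort labels.
#'
#' @param segmentedList named list of [SegmentedProfile-class] objects on
#'   identical clone grids; names are sample ids.
#' @param cohorts cohort label per sample (recycled names checked).
#' @return A [StateMatrix-class]; entries missing after QC are `NA` and the
#'   `observed` mask is `FALSE` there.
#' @export
buildStateMatrix <- function(segmentedList, cohorts) {
    stopifnot(length(segmentedList) >= 1L,
              length(cohorts) == length(segmentedList))
    ref <- segmentedList[[1L]]@clones
    st <- vapply(segmentedList, callStates, integer(length(ref)))
    if (is.null(colnames(st)))
        colnames(st) <- vapply(segmentedList, sampleName, character(1))
    new("StateMatrix", states = st, clones = ref,
        cohorts = as.factor(cohorts), observed = !is.na(st))
}

#' Impute missing states from genomic neighbours
#'
#' Each missing entry takes the state of the nearest originally-observed
#' clone of the same sample and chromosome whose midpoint lies within
#' `windowBp`; entries with no such neighbour stay missing. When the nearest
#' neighbours on both sides are exactly equidistant, agreement between them
#' keeps their common state and disagreement yields neutral. Donors are
#' always originally measured entries (never previously imputed ones), so
#' the operation is idempotent and observed entries are never altered.
#'
#' @param m a [StateMatrix-class].
#' @param windowBp maximal midpoint distance for a donor (default 10 Mb).
#' @return The imputed [StateMatrix-class] (the `observed` mask is retained).
#' @export
imputeMissingStates <- function(m, windowBp = 1e7) {
    stopifnot(is(m, "StateMatrix"), windowBp > 0)
    mid <- (start(m@clones) - 1 + end(m@clones)) / 2
    chrom <- as.character(seqnames(m@clones))
    st <- m@states
    for (j in seq_len(ncol(st))) {
        obs <- which(m@observed[, j])
        nas <- which(is.na(st[, j]))
        if (!length(nas) || !length(obs)) next
        for (i in nas) {
            cand <- obs[chrom[obs] == chrom[i]]
            if (!length(cand)) next
            d <- abs(mid[cand] - mid[i])
            ok <- d <= windowBp
            if (!any(ok)) next
            cand <- cand[ok]; d <- d[ok]
            nearest <- cand[d == min(d)]
            vals <- unique(st[nearest, j])
            st[i, j] <- if (length(vals) == 1L) vals else 0L
        }
    }
    m@states <- st
    m
}

#' Per-clone alteration frequencies for one cohort
#'
#' @param m a [StateMatrix-class].
#' @param cohort cohort label.
#' @return `data.frame` per clone with `gainFreq`, `lossFreq` (fractions of
#'   the cohort's non-missing samples with state +1 / -1; `NaN` where every
#'   sample is missing), and `nInformative`.
#' @export
alterationFrequency <- function(m, cohort) {
    stopifnot(is(m, "StateMatrix"))
    sel <- m@cohorts == cohort
    if (!any(sel)) stop("empty cohort '", cohort, "'")
    sub <- m@states[, sel, drop = FALSE]
    nInf <- rowSums(!is.na(sub))
    cbind(.bpBounds(m@clones),
          data.frame(
              gainFreq = rowSums(sub == 1L, na.rm = TRUE) / nInf,
              lossFreq = rowSums(sub == -1L, na.rm = TRUE) / nInf,
              nInformative = nInf))
}

#' Aggregate clones into regions of consistent copy-number status
#'
#' Partitions the clone order into maximal runs in which every adjacent
#' clone pair agrees in state in at least `similarity` of the cohort's
#' samples (pairs where either entry is missing are excluded from the
#' denominator; a pair with no informative sample is treated as agreeing).
#' Chromosome boundaries always split regions.
#'
#' @param m a [StateMatrix-class].
#' @param cohort cohort label whose samples define the agreement.
#' @param similarity minimal agreement fraction (default 0.90).
#' @return integer vector of region ids (one per clone, consecutive runs).
#' @export
aggregateRegions <- function(m, cohort, similarity = 0.90) {
    stopifnot(is(m, "StateMatrix"), similarity > 0, similarity <= 1)
    sel <- m@cohorts == cohort
    if (!any(sel)) stop("empty cohort '", cohort, "'")
    sub <- m@states[, sel, drop = FALSE]
    n <- nrow(sub)
    if (n == 1L) return(1L)
    agree <- sub[-n, , drop = FALSE] == sub[-1L, , drop = FALSE]
    num <- rowSums(agree, na.rm = TRUE)
    den <- rowSums(!is.na(agree))
    sim <- ifelse(den == 0L, 1, num / den)
    chrom <- as.character(seqnames(m@clones))
    boundary <- sim < similarity | chrom[-n] != chrom[-1L]
    cumsum(c(TRUE, boundary))
}

#' Exact Fisher test on a 3x2 contingency table
#'
#' Exact conditional test for association in a 3x2 table (copy-number state
#' by cohort): the p-value is the total probability, under the multivariate
#' hypergeometric distribution with the observed margins, of all tables at
#' most as probable as the observed one. Implemented by direct enumeration
#' of the two free cells; a relative tolerance of 1e-7 groups
#' floating-point ties.
#'
#' @param tab 3x2 matrix of non-negative integer counts
#'   (rows gain/neutral/loss, columns the two cohorts).
#' @return the exact p-value in (0, 1].
#' @export
fisher3x2 <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(3L, 2L)), all(tab >= 0),
              all(tab == round(tab)))
    N <- sum(tab)
    if (N == 0) stop("zero grand total")
    r <- rowSums(tab); c1 <- sum(tab[, 1L])
    # enumerate (a1, a2) = column-1 counts of rows 1 and 2; row 3 follows
    n1 <- min(r[1L], c1) + 1L; n2 <- min(r[2L], c1) + 1L
    a1 <- rep.int(0:(n1 - 1L), n2)
    a2 <- rep(0:(n2 - 1L), each = n1)
    a3 <- c1 - a1 - a2
    ok <- a3 >= 0 & a3 <= r[3L]
    logp <- lchoose(r[1L], a1[ok]) + lchoose(r[2L], a2[ok]) +
        lchoose(r[3L], a3[ok]) - lchoose(N, c1)
    obs <- lchoose(r[1L], tab[1L, 1L]) + lchoose(r[2L], tab[2L, 1L]) +
        lchoose(r[3L], tab[3L, 1L]) - lchoose(N, c1)
    min(1, sum(exp(logp[logp <= obs + 1e-7])))
}
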