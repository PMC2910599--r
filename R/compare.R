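# Two-cohort disparity analysis: region aggregation, per-region exact
# testing, BH correction, merging and frequency filtering.

# internal: per-region representative state per sample (majority of member
# clones; ties -> neutral; all-missing -> NA)
.representativeStates <- function(states, idx) {
    sub <- states[idx, , drop = FALSE]
    g <- colSums(sub == 1L, na.rm = TRUE)
    l <- colSums(sub == -1L, na.rm = TRUE)
    z <- colSums(sub == 0L, na.rm = TRUE)
    rep <- ifelse(g + l + z == 0L, NA_integer_,
           ifelse(g > pmax(z, l), 1L,
           ifelse(l > pmax(z, g), -1L, 0L)))
    as.integer(rep)
}

# internal: 3x2 count table (rows gain/neutral/loss) from representative
# states of the two cohorts
.regionTable <- function(repStates, selA, selB) {
    cntA <- c(sum(repStates[selA] == 1L, na.rm = TRUE),
              sum(repStates[selA] == 0L, na.rm = TRUE),
              sum(repStates[selA] == -1L, na.rm = TRUE))
    cntB <- c(sum(repStates[selB] == 1L, na.rm = TRUE),
              sum(repStates[selB] == 0L, na.rm = TRUE),
              sum(repStates[selB] == -1L, na.rm = TRUE))
    matrix(c(cntA, cntB), nrow = 3L,
           dimnames = list(c("gain", "neutral", "loss"), c("A", "B")))
}

# internal: summarise one region (clone index set) into a result row
.regionRow <- function(m, idx, selA, selB) {
    rep <- .representativeStates(m@states, idx)
    tab <- .regionTable(rep, selA, selB)
    nA <- sum(!is.na(rep[selA])); nB <- sum(!is.na(rep[selB]))
    fGainA <- tab["gain", "A"] / nA; fGainB <- tab["gain", "B"] / nB
    fLossA <- tab["loss", "A"] / nA; fLossB <- tab["loss", "B"] / nB
    # direction = state with the largest absolute frequency difference
    dGain <- abs(fGainA - fGainB); dLoss <- abs(fLossA - fLossB)
    if (dGain >= dLoss) {
        direction <- "gain"; fA <- fGainA; fB <- fGainB
    } else {
        direction <- "loss"; fA <- fLossA; fB <- fLossB
    }
    bp <- .bpBounds(m@clones[idx])
    list(row = data.frame(
             chrom = bp$chrom[1L], start = min(bp$start), end = max(bp$end),
             nClones = length(idx),
             startIndex = min(idx), endIndex = max(idx),
             gainA = tab[1L, 1L], neutralA = tab[2L, 1L], lossA = tab[3L, 1L],
             gainB = tab[1L, 2L], neutralB = tab[2L, 2L], lossB = tab[3L, 2L],
             p = if (sum(tab) > 0) fisher3x2(tab) else NA_real_,
             direction = direction, freqA = fA, freqB = fB),
         table = tab, clones = idx)
}

#' Identify regions of differential copy-number alteration between cohorts
#'
#' Full disparity pipeline on an (imputed) [StateMatrix-class]:
#' (i) clones are aggregated into regions separately per cohort (adjacent
#' pairs must agree in at least `similarity` of samples) and the two
#' partitions are intersected; (ii) each sample is reduced to one
#' representative state per region (majority of member clones, ties
#' neutral); (iii) each region's 3x2 state-by-cohort table is tested with
#' the exact Fisher test; (iv) Benjamini-Hochberg correction over the
#' number of distinct regions; (v) regions with adjusted p <= `alpha` are
#' kept; (vi) adjacent kept regions within `mergeGapBp` whose direction
#' (excess state and excess cohort) matches are merged, with counts and
#' frequencies recomputed over the merged clones and the smallest member
#' adjusted p retained; (vii) regions must be altered, in the region's
#' direction, in more than `minGroupFrequency` of the samples of at least
#' one cohort, with a between-cohort difference above
#' `minFrequencyDifference`.
#'
#' @param m a [StateMatrix-class] (run [imputeMissingStates()] first).
#' @param cohortA,cohortB the two cohort labels to compare.
#' @param similarity adjacent-clone agreement needed to stay in one region
#'   (default 0.90).
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @param mergeGapBp maximal gap for merging concordant regions (default
#'   1 Mb).
#' @param minGroupFrequency minimal direction-specific alteration frequency
#'   in the more-altered cohort (default 0.20, exceeded strictly).
#' @param minFrequencyDifference minimal between-cohort frequency
#'   difference (default 0.10, exceeded strictly).
#' @return `data.frame` of surviving regions (possibly empty), sorted by
#'   position, with bp bounds, clone counts, the full 3x2 count table in
#'   columns, `p`, `padj`, `direction` (`"gain"`/`"loss"`),
#'   `higherCohort`, and per-cohort direction frequencies `freqA`, `freqB`.
#'   Attribute `"audit"` carries the pre-filter region table with all
#'   tested regions and their p-values.
#' @export
compareCohorts <- function(m, cohortA, cohortB,
                           similarity = 0.90, alpha = 0.01,
                           mergeGapBp = 1e6, minGroupFrequency = 0.20,
                           minFrequencyDifference = 0.10) {
    stopifnot(is(m, "StateMatrix"))
    selA <- m@cohorts == cohortA
    selB <- m@cohorts == cohortB
    if (sum(selA) < 2L || sum(selB) < 2L)
        stop("each cohort needs at least two samples")
    # (i) intersection of the two cohort partitions (union of boundaries)
    ridA <- aggregateRegions(m, cohortA, similarity)
    ridB <- aggregateRegions(m, cohortB, similarity)
    rid <- cumsum(c(TRUE, diff(ridA) != 0L | diff(ridB) != 0L))
    regions <- split(seq_along(rid), rid)
    # (ii)+(iii) representative states and exact tests
    rows <- lapply(regions, function(idx) .regionRow(m, idx, selA, selB))
    res <- do.call(rbind, c(lapply(rows, `[[`, "row"),
                            list(make.row.names = FALSE)))
    # (iv) BH over the number of distinct regions
    res$padj <- stats::p.adjust(res$p, method = "BH")
    audit <- res
    # (v) significance filter
    keep <- which(!is.na(res$padj) & res$padj <= alpha)
    res <- res[keep, , drop = FALSE]
    cloneSets <- lapply(rows[keep], `[[`, "clones")
    # (vi) merge adjacent concordant regions within the gap
    if (nrow(res) > 1L) {
        res$higherCohort <- ifelse(res$freqA >= res$freqB, cohortA, cohortB)
        i <- 1L
        while (i < nrow(res)) {
            gap <- res$start[i + 1L] - res$end[i]
            if (res$chrom[i] == res$chrom[i + 1L] && gap <= mergeGapBp &&
                res$direction[i] == res$direction[i + 1L] &&
                res$higherCohort[i] == res$higherCohort[i + 1L]) {
                idx <- c(cloneSets[[i]], cloneSets[[i + 1L]])
                merged <- .regionRow(m, idx, selA, selB)$row
                merged$padj <- min(res$padj[i], res$padj[i + 1L])
                merged$higherCohort <-
                    ifelse(merged$freqA >= merged$freqB, cohortA, cohortB)
                res <- rbind(merged, res[-(i:(i + 1L)), , drop = FALSE])
                res <- res[order(res$chrom, res$start), , drop = FALSE]
                cloneSets <- c(list(idx), cloneSets[-(i:(i + 1L))])
                ord <- order(vapply(cloneSets, min, 1L))
                cloneSets <- cloneSets[ord]
            } else i <- i + 1L
        }
    } else if (nrow(res) == 1L) {
        res$higherCohort <- ifelse(res$freqA >= res$freqB, cohortA, cohortB)
    }
    # (vii) frequency filters, direction-specific
    if (nrow(res)) {
        ok <- pmax(res$freqA, res$freqB) > minGroupFrequency &
              abs(res$freqA - res$freqB) > minFrequencyDifference
        res <- res[ok, , drop = FALSE]
    }
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "audit") <- audit
    res
}
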