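# Expression statistics and copy-number / expression integration.

# internal: one-tailed Mann-Whitney p for greater-than alternative,
# exact when feasible (tie-free, both groups < 50), normal approximation
# with tie and continuity correction otherwise; constant inputs -> p = 1
.mwuGreater <- function(x, y) {
    if (length(unique(c(x, y))) == 1L) return(list(p = 1, constant = TRUE))
    p <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "greater")$p.value)
    list(p = p, constant = FALSE)
}

#' One-tailed differential expression between two cohorts
#'
#' Per-probe one-tailed Mann-Whitney U test of the alternative that
#' expression in `cohortB` exceeds that in `cohortA`, with
#' Benjamini-Hochberg correction over all tested probes. Exact p-values are
#' used whenever the data are tie-free and small enough; otherwise the
#' normal approximation with tie and continuity correction applies.
#' A probe constant across all samples gets p = 1 and is flagged.
#'
#' @param panel an [ExpressionPanel-class].
#' @param cohortA,cohortB cohort labels; the alternative is B > A.
#' @return `data.frame` with `probeId`, `gene`, `p`, `padj`, `constant`.
#' @export
diffExpression <- function(panel, cohortA, cohortB) {
    stopifnot(is(panel, "ExpressionPanel"))
    selA <- panel@cohorts == cohortA
    selB <- panel@cohorts == cohortB
    if (sum(selA) < 2L || sum(selB) < 2L)
        stop("each cohort needs at least two samples")
    res <- lapply(seq_len(nrow(panel@exprs)), function(i) {
        .mwuGreater(panel@exprs[i, selB], panel@exprs[i, selA])
    })
    out <- data.frame(
        probeId = panel@probeMap$probeId,
        gene = panel@probeMap$gene,
        p = vapply(res, `[[`, numeric(1), "p"),
        constant = vapply(res, `[[`, logical(1), "constant"))
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out
}

#' Collapse probe-level results to gene level
#'
#' When several probes map to the same gene, keeps the probe with the
#' lowest p-value (`rule = "min_p"`) or with the highest mean intensity
#' across all samples (`rule = "max_intensity"`, requiring a
#' `meanIntensity` column).
#'
#' @param probeResults `data.frame` with at least `probeId` and `gene`, plus
#'   `p` (for `min_p`) or `meanIntensity` (for `max_intensity`).
#' @param rule `"min_p"` or `"max_intensity"`.
#' @return one row per gene; the chosen probe id is retained in `probeId`.
#' @export
collapseProbes <- function(probeResults, rule = c("min_p", "max_intensity")) {
    rule <- match.arg(rule)
    key <- switch(rule,
        min_p = {
            stopifnot("p" %in% names(probeResults))
            probeResults$p
        },
        max_intensity = {
            stopifnot("meanIntensity" %in% names(probeResults))
            -probeResults$meanIntensity
        })
    o <- order(probeResults$gene, key)
    picked <- o[!duplicated(probeResults$gene[o])]
    out <- probeResults[sort(picked), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Windowed, Z-transformed copy-number signal for one sample
#'
#' Computes a moving average of the combined log2 ratios over genomic
#' windows of `windowBp` tiling each chromosome from position 0, weighting
#' each overlapping non-missing clone by its bp overlap with the window,
#' then standardises the windowed values across the whole profile
#' (subtract mean, divide by SD). Windows without clone coverage are `NA`.
#'
#' @param profile an [AcghProfile-class].
#' @param windowBp window width in bp (default 10 kb).
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open
#'   window bounds), `value` (windowed mean) and `z`; if the windowed
#'   signal has zero variance the `z` column is `NA` and the result carries
#'   attribute `zeroVariance = TRUE`.
#' @export
windowedZscore <- function(profile, windowBp = 1e4) {
    stopifnot(is(profile, "AcghProfile"), windowBp > 0)
    keep <- which(!profile@missing)
    clones <- profile@clones[keep]
    vals <- profile@log2Ratio[keep]
    out <- list()
    for (ch in unique(as.character(seqnames(profile@clones)))) {
        sel <- as.character(seqnames(clones)) == ch
        chromEnd <- max(end(profile@clones[
            as.character(seqnames(profile@clones)) == ch]))
        ws <- seq(0L, chromEnd - 1L, by = windowBp)
        we <- pmin(ws + windowBp, chromEnd)
        win <- GRanges(ch, IRanges(ws + 1L, we))
        value <- rep(NA_real_, length(win))
        if (any(sel)) {
            hits <- findOverlaps(win, clones[sel])
            ov <- width(pintersect(win[queryHits(hits)],
                                   granges(clones[sel])[subjectHits(hits)]))
            wsum <- tapply(ov, queryHits(hits), sum)
            vsum <- tapply(ov * vals[sel][subjectHits(hits)],
                           queryHits(hits), sum)
            value[as.integer(names(wsum))] <- vsum / wsum
        }
        out[[ch]] <- data.frame(chrom = ch, start = ws, end = we,
                                value = value)
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    mu <- mean(res$value, na.rm = TRUE)
    sdv <- stats::sd(res$value, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) {
        res$z <- NA_real_
        attr(res, "zeroVariance") <- TRUE
    } else {
        res$z <- (res$value - mu) / sdv
        attr(res, "zeroVariance") <- FALSE
    }
    res
}

#' Per-gene average dosage Z-scores across samples
#'
#' For each sample, averages the windowed Z-scores (see [windowedZscore()])
#' over the windows overlapping each gene interval.
#'
#' @param profiles named list of [AcghProfile-class] objects.
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param windowBp window width (default 10 kb).
#' @return numeric matrix genes x samples of average Z-scores.
#' @export
geneDosageZ <- function(profiles, genes, windowBp = 1e4) {
    zs <- vapply(profiles, function(p) {
        w <- windowedZscore(p, windowBp)
        vapply(seq_len(nrow(genes)), function(g) {
            sel <- w$chrom == genes$chrom[g] &
                   w$end > genes$start[g] & w$start < genes$end[g]
            mean(w$z[sel], na.rm = TRUE)
        }, numeric(1))
    }, numeric(nrow(genes)))
    zs <- matrix(zs, nrow = nrow(genes),
                 dimnames = list(genes$gene, names(profiles)))
    zs
}

#' Per-gene categorical dosage status across samples
#'
#' Majority copy-number state (ties neutral) of the clones overlapping each
#' gene interval, per sample, from a [StateMatrix-class].
#'
#' @param m a [StateMatrix-class] (imputed).
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @return integer matrix genes x samples with entries -1/0/1/NA.
#' @export
geneDosageStatus <- function(m, genes) {
    bounds <- .bpBounds(m@clones)
    out <- matrix(NA_integer_, nrow(genes), ncol(m@states),
                  dimnames = list(genes$gene, colnames(m@states)))
    for (g in seq_len(nrow(genes))) {
        idx <- which(bounds$chrom == genes$chrom[g] &
                     bounds$end > genes$start[g] &
                     bounds$start < genes$end[g])
        if (!length(idx)) next
        out[g, ] <- .representativeStates(m@states, idx)
    }
    out
}

#' Spearman dosage-expression correlation for one gene
#'
#' Spearman correlation (average ranks for ties) between per-sample dosage
#' Z-scores and expression values, with the one-tailed p-value for a
#' positive correlation. Exact p-values are used for tie-free small
#' samples.
#'
#' @param z numeric vector of dosage Z-scores.
#' @param e numeric vector of expression values (same samples).
#' @return list with `rho`, `p`, `n`.
#' @export
dosageCorrelation <- function(z, e) {
    ok <- !is.na(z) & !is.na(e)
    if (sum(ok) < 4L)
        stop("need at least 4 paired samples for the dosage correlation")
    if (stats::sd(z[ok]) == 0 || stats::sd(e[ok]) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(
        stats::cor.test(z[ok], e[ok], method = "spearman",
                        alternative = "greater"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Gain/amplification versus neutral expression test for one gene
#'
#' One-tailed Mann-Whitney test of higher expression in samples with
#' copy-number gain/amplification than in copy-number-neutral samples;
#' samples with loss are excluded (their count is reported). Alongside the
#' p-value, guard flags record whether the gain group's median and mean
#' exceed the neutral group's.
#'
#' @param e expression values per sample.
#' @param status per-sample dosage status (-1/0/1, NA allowed).
#' @return list with `testable`, `p`, `medianHigher`, `meanHigher`,
#'   `nGain`, `nNeutral`, `nLossExcluded`.
#' @export
dosageGroupTest <- function(e, status) {
    stopifnot(length(e) == length(status))
    ok <- !is.na(e) & !is.na(status)
    gain <- e[ok & status == 1L]
    neut <- e[ok & status == 0L]
    nLoss <- sum(ok & status == -1L)
    if (!length(gain) || !length(neut))
        return(list(testable = FALSE, p = NA_real_, medianHigher = NA,
                    meanHigher = NA, nGain = length(gain),
                    nNeutral = length(neut), nLossExcluded = nLoss))
    list(testable = TRUE,
         p = .mwuGreater(gain, neut)$p,
         medianHigher = stats::median(gain) > stats::median(neut),
         meanHigher = mean(gain) > mean(neut),
         nGain = length(gain), nNeutral = length(neut),
         nLossExcluded = nLoss)
}

#' Tumor versus normal expression elevation for one gene
#'
#' Fold change is the ratio of group medians on the linear scale (values on
#' a log scale are exponentiated first); the p-value is the one-tailed
#' Mann-Whitney test of tumor > normal.
#'
#' @param eTumor,eNormal expression values for the tumor and normal groups.
#' @param scale `"log10"`, `"log2"` or `"linear"` (scale of the inputs).
#' @return list with `fold` (`NA` flagged when a linear median is
#'   non-positive), `p`, `foldDefined`.
#' @export
tumorVsNormal <- function(eTumor, eNormal, scale = "log10") {
    stopifnot(length(eTumor) >= 2L, length(eNormal) >= 2L)
    lin <- switch(scale,
        log10 = function(x) 10^x,
        log2 = function(x) 2^x,
        linear = identity,
        stop("unknown scale '", scale, "'"))
    mT <- stats::median(lin(eTumor)); mN <- stats::median(lin(eNormal))
    defined <- mT > 0 && mN > 0
    list(fold = if (defined) mT / mN else NA_real_,
         p = .mwuGreater(eTumor, eNormal)$p,
         foldDefined = defined)
}

#' Dosage-integration statistics for a panel of genes
#'
#' Convenience wrapper running, within one tumor cohort, the Spearman
#' dosage correlation (on windowed Z-scores) and the gain-versus-neutral
#' group test for every gene, with BH correction across genes for each of
#' the two methods, plus the tumor-versus-normal comparison against a
#' normal cohort.
#'
#' @param profiles named list of [AcghProfile-class] for the tumor cohort
#'   samples (must match expression sample names).
#' @param m imputed [StateMatrix-class] covering the same samples.
#' @param panel an [ExpressionPanel-class] containing the tumor cohort and
#'   the normal cohort.
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param tumorCohort,normalCohort cohort labels in `panel`.
#' @param windowBp window width for the Z-score method.
#' @return `data.frame`, one row per gene: `rho`, `rhoP`, `rhoPadj`,
#'   `groupTestable`, `groupP`, `groupPadj`, `medianHigher`, `meanHigher`,
#'   `nLossExcluded`, `fold`, `tvnP`, `tvnPadj`.
#' @export
integrateDosage <- function(profiles, m, panel, genes,
                            tumorCohort, normalCohort, windowBp = 1e4) {
    stopifnot(is(panel, "ExpressionPanel"))
    tumorSamples <- colnames(panel@exprs)[panel@cohorts == tumorCohort]
    stopifnot(all(tumorSamples %in% names(profiles)),
              all(tumorSamples %in% colnames(m@states)))
    zs <- geneDosageZ(profiles[tumorSamples], genes, windowBp)
    status <- geneDosageStatus(m, genes)[, tumorSamples, drop = FALSE]
    exprT <- panel@exprs[, tumorSamples, drop = FALSE]
    exprN <- panel@exprs[, panel@cohorts == normalCohort, drop = FALSE]
    pm <- panel@probeMap
    rows <- lapply(seq_len(nrow(genes)), function(g) {
        probes <- which(pm$gene == genes$gene[g])
        if (!length(probes))
            return(data.frame(gene = genes$gene[g], rho = NA_real_,
                              rhoP = NA_real_, groupTestable = NA,
                              groupP = NA_real_, medianHigher = NA,
                              meanHigher = NA, nLossExcluded = NA_integer_,
                              fold = NA_real_, tvnP = NA_real_))
        # highest mean intensity probe represents the gene
        pr <- probes[which.max(rowMeans(panel@exprs[probes, , drop = FALSE]))]
        eT <- exprT[pr, ]; eN <- exprN[pr, ]
        dc <- dosageCorrelation(zs[g, ], eT)
        gt <- dosageGroupTest(eT, status[g, ])
        tv <- tumorVsNormal(eT, eN, panel@scale)
        data.frame(gene = genes$gene[g], rho = dc$rho, rhoP = dc$p,
                   groupTestable = gt$testable, groupP = gt$p,
                   medianHigher = gt$medianHigher, meanHigher = gt$meanHigher,
                   nLossExcluded = gt$nLossExcluded,
                   fold = tv$fold, tvnP = tv$p)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$rhoPadj <- stats::p.adjust(out$rhoP, method = "BH")
    out$groupPadj <- stats::p.adjust(out$groupP, method = "BH")
    out$tvnPadj <- stats::p.adjust(out$tvnP, method = "BH")
    out
}
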