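#' Candidate-driver filtering cascade
#'
#' Combines the disparity regions, the two-cohort differential expression
#' results, the two dosage-integration methods and the tumor-versus-normal
#' comparison into a per-gene audit of five criteria:
#'
#' 1. `disparity_region`: the gene interval overlaps a reported disparity
#'    region;
#' 2. `differential_expression`: BH-adjusted one-tailed p <= `alphaDE` for
#'    higher expression in the amplified lineage;
#' 3. `dosage_correlation`: Spearman rho > `rhoMin` with BH-adjusted
#'    one-tailed p < `alphaRho`;
#' 4. `dosage_group`: testable gain/amplification versus neutral comparison
#'    with BH-adjusted p <= `alphaGroup` and both median and mean guards;
#' 5. `tumor_vs_normal`: fold change > `foldMin` with BH-adjusted p <=
#'    `alphaTvn`.
#'
#' The final candidate flag is the conjunction of all five. Genes failing
#' exactly one criterion are reported as near-misses with the failed
#' criterion named; genes absent from any upstream result set are flagged
#' untestable, never dropped.
#'
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param regions disparity regions from [compareCohorts()].
#' @param de gene-level differential expression (after [collapseProbes()]),
#'   with columns `gene`, `padj`.
#' @param dosage output of [integrateDosage()].
#' @param rhoMin minimal Spearman correlation (default 0.75).
#' @param alphaDE,alphaRho,alphaGroup,alphaTvn significance cutoffs
#'   (defaults 0.01, 0.01, 0.05, 0.01).
#' @param foldMin minimal tumor/normal fold change (default 2).
#' @param cisAmpFraction optional named vector: per-gene fraction of an
#'   early-lesion (CIS-like) cohort with high-level amplification covering
#'   the gene; reported, never used as a filter.
#' @return `data.frame`, one row per gene, with all statistics, one logical
#'   `pass_*` column per criterion, `nFailed`, `candidate`, `nearMiss`,
#'   `failedCriterion` (the named criterion for near-misses), and
#'   `untestable`. Candidates sort first, by decreasing rho.
#' @export
runCascade <- function(genes, regions, de, dosage,
                       rhoMin = 0.75, alphaDE = 0.01, alphaRho = 0.01,
                       alphaGroup = 0.05, alphaTvn = 0.01, foldMin = 2,
                       cisAmpFraction = NULL) {
    criteria <- c("disparity_region", "differential_expression",
                  "dosage_correlation", "dosage_group", "tumor_vs_normal")
    out <- genes[, c("gene", "chrom", "start", "end")]
    inRegion <- vapply(seq_len(nrow(genes)), function(g) {
        if (is.null(regions) || !nrow(regions)) return(FALSE)
        any(regions$chrom == genes$chrom[g] &
            regions$end > genes$start[g] & regions$start < genes$end[g])
    }, logical(1))
    regionId <- vapply(seq_len(nrow(genes)), function(g) {
        if (is.null(regions) || !nrow(regions)) return(NA_integer_)
        hit <- which(regions$chrom == genes$chrom[g] &
                     regions$end > genes$start[g] &
                     regions$start < genes$end[g])
        if (length(hit)) hit[1L] else NA_integer_
    }, integer(1))
    dm <- match(out$gene, de$gene)
    xm <- match(out$gene, dosage$gene)
    out$regionId <- regionId
    out$dePadj <- de$padj[dm]
    out$rho <- dosage$rho[xm]
    out$rhoPadj <- dosage$rhoPadj[xm]
    out$groupTestable <- dosage$groupTestable[xm]
    out$groupPadj <- dosage$groupPadj[xm]
    out$medianHigher <- dosage$medianHigher[xm]
    out$meanHigher <- dosage$meanHigher[xm]
    out$fold <- dosage$fold[xm]
    out$tvnPadj <- dosage$tvnPadj[xm]
    out$untestable <- is.na(dm) | is.na(xm)

    isTRUEv <- function(x) !is.na(x) & x
    out$pass_disparity_region <- inRegion
    out$pass_differential_expression <- isTRUEv(out$dePadj <= alphaDE)
    out$pass_dosage_correlation <-
        isTRUEv(out$rho > rhoMin & out$rhoPadj < alphaRho)
    out$pass_dosage_group <- isTRUEv(out$groupTestable) &
        isTRUEv(out$groupPadj <= alphaGroup) &
        isTRUEv(out$medianHigher) & isTRUEv(out$meanHigher)
    out$pass_tumor_vs_normal <-
        isTRUEv(out$fold > foldMin & out$tvnPadj <= alphaTvn)

    passCols <- paste0("pass_", criteria)
    passMat <- as.matrix(out[, passCols])
    out$nFailed <- rowSums(!passMat)
    out$candidate <- out$nFailed == 0L & !out$untestable
    out$nearMiss <- out$nFailed == 1L & !out$untestable
    out$failedCriterion <- ifelse(out$nearMiss,
        criteria[apply(!passMat, 1L, which.max)], NA_character_)
    if (!is.null(cisAmpFraction))
        out$cisAmpFraction <- unname(cisAmpFraction[out$gene])
    o <- order(-out$candidate, -out$nearMiss,
               -ifelse(is.na(out$rho), -Inf, out$rho))
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}
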