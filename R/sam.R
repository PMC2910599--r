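# SAM-style two-class unpaired permutation differential expression.

# internal: vectorised d-statistics for an expression matrix split into two
# column index sets; d = (mean1 - mean2) / (s + s0) with the pooled
# standard error s of the unpaired two-class statistic
.samD <- function(x, idx1, idx2, s0) {
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(x[, idx1, drop = FALSE])
    m2 <- rowMeans(x[, idx2, drop = FALSE])
    ss1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    list(d = (m1 - m2) / (s + s0), s = s)
}

# internal: fudge factor chosen on a percentile grid by minimising the
# coefficient of variation of the d-statistic spread across s-quantile bins
.autoS0 <- function(r, s) {
    qs <- stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE)
    nbin <- min(20L, max(2L, length(s) %/% 10L))
    bins <- cut(rank(s, ties.method = "first"), nbin, labels = FALSE)
    cv <- vapply(qs, function(s0) {
        d <- r / (s + s0)
        v <- tapply(d, bins, stats::mad)
        if (mean(v) == 0) Inf else stats::sd(v) / mean(v)
    }, numeric(1))
    qs[which.min(cv)]
}

#' Select extreme-expresser sample groups for a gene
#'
#' Sorts samples by the expression of the given gene, using the probe with
#' the highest mean intensity across the whole panel when several probes
#' map to it, and returns the `nExtreme` highest and lowest samples. Ties
#' at the group boundary are broken by the stable sample order of the
#' panel.
#'
#' @param panel an [ExpressionPanel-class].
#' @param gene gene identifier present in the probe map.
#' @param nExtreme group size per tail (default 10).
#' @return list with `high` and `low` character vectors of sample names,
#'   and `probeId`, the representative probe used.
#' @export
selectExtremes <- function(panel, gene, nExtreme = 10) {
    stopifnot(is(panel, "ExpressionPanel"), nExtreme >= 1)
    probes <- which(panel@probeMap$gene == gene)
    if (!length(probes)) stop("gene '", gene, "' not in probe map")
    if (ncol(panel@exprs) < 2 * nExtreme)
        stop("need at least ", 2 * nExtreme, " samples")
    pr <- probes[which.max(rowMeans(panel@exprs[probes, , drop = FALSE]))]
    v <- panel@exprs[pr, ]
    o <- order(v, decreasing = TRUE)  # stable for ties
    samples <- colnames(panel@exprs)
    list(high = samples[o[seq_len(nExtreme)]],
         low = rev(samples[o[seq(length(o) - nExtreme + 1L, length(o))]]),
         probeId = panel@probeMap$probeId[pr])
}

#' SAM two-class unpaired analysis
#'
#' Computes the moderated d-statistic `d = (mean1 - mean2) / (s + s0)` per
#' gene and estimates q-values from label permutations: for each observed
#' `|d|` threshold, the false discovery rate is `pi0` times the median
#' permutation count of statistics exceeding the threshold divided by the
#' observed count, and a gene's q-value is the minimum FDR over all
#' thresholds that would call it. `pi0` is estimated from the fraction of
#' observed statistics inside the permutation interquartile range. When
#' the number of distinct group-1 assignments is at most `nPermutations`
#' the permutation set is enumerated exhaustively; otherwise random
#' permutations are drawn under the given seed.
#'
#' @param x genes x samples numeric matrix (row names = genes).
#' @param group1,group2 disjoint sample (column) name or index vectors.
#' @param s0 fudge factor; a number, or `"auto"` for the percentile rule
#'   (default `"auto"`).
#' @param nPermutations permutation count (default 1000; at least 100 is
#'   recommended for stable q-values).
#' @param seed integer seed for the permutation draw.
#' @return `data.frame` with `gene`, `d`, `s`, `q`, sorted as the input;
#'   attributes `s0`, `pi0` and `nPermutationsUsed`.
#' @export
samTwoClass <- function(x, group1, group2, s0 = "auto",
                        nPermutations = 1000, seed = 1) {
    x <- as.matrix(x)
    if (is.character(group1)) group1 <- match(group1, colnames(x))
    if (is.character(group2)) group2 <- match(group2, colnames(x))
    stopifnot(!anyNA(group1), !anyNA(group2),
              length(intersect(group1, group2)) == 0L,
              length(group1) >= 2L, length(group2) >= 2L)
    m <- nrow(x)
    obs <- .samD(x, group1, group2, 0)
    if (identical(s0, "auto")) {
        r <- obs$d * obs$s  # numerator of d
        s0 <- .autoS0(r, obs$s)
    }
    stopifnot(is.numeric(s0), s0 >= 0)
    if (s0 == 0 && any(obs$s == 0))
        warning("genes constant in both groups with s0 = 0: d undefined")
    d <- .samD(x, group1, group2, s0)$d

    # canonical column order so the permutation null is invariant under
    # swapping the two group labels
    cols <- sort(c(group1, group2))
    n1 <- length(group1)
    total <- choose(length(cols), n1)
    if (total <= nPermutations) {
        sel <- utils::combn(length(cols), n1, simplify = FALSE)
    } else {
        set.seed(seed)
        sel <- replicate(nPermutations,
                         sample.int(length(cols), n1), simplify = FALSE)
    }
    permAbs <- lapply(sel, function(ix) {
        g1 <- cols[ix]; g2 <- cols[-ix]
        abs(.samD(x, g1, g2, s0)$d)
    })
    permAll <- unlist(lapply(sel, function(ix) {
        .samD(x, cols[ix], cols[-ix], s0)$d
    }), use.names = FALSE)
    qr <- stats::quantile(permAll, c(0.25, 0.75), names = FALSE)
    pi0 <- min(1, sum(d >= qr[1] & d <= qr[2]) / (0.5 * m))

    o <- order(abs(d), decreasing = TRUE)
    thr <- abs(d)[o]
    called <- seq_len(m)
    # per permutation, count statistics >= each threshold
    cnt <- vapply(permAbs, function(a) {
        sa <- sort(a)
        length(a) - findInterval(thr - 1e-12, sa)
    }, numeric(m))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = m)
    medCnt <- apply(cnt, 1L, stats::median)
    fdr <- pmin(1, pi0 * medCnt / called)
    q <- rev(cummin(rev(fdr)))
    # tied |d| values share the most permissive q
    qFull <- numeric(m)
    qFull[o] <- q
    for (tv in unique(thr[duplicated(thr)]))
        qFull[abs(d) == tv] <- max(qFull[abs(d) == tv])
    out <- data.frame(gene = if (is.null(rownames(x)))
                          paste0("g", seq_len(m)) else rownames(x),
                      d = d, s = .samD(x, group1, group2, 0)$s, q = qFull)
    attr(out, "s0") <- s0
    attr(out, "pi0") <- pi0
    attr(out, "nPermutationsUsed") <- length(sel)
    out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
    names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
    sets
}

#' One-sided hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of `hits` within
#' `universe` with the hypergeometric tail probability, BH-corrected
#' across sets.
#'
#' @param hits character vector of selected genes.
#' @param universe character vector of all testable genes.
#' @param sets named list of gene sets (e.g. from [readGmt()]).
#' @return `data.frame` with `set`, `nSet`, `nOverlap`, `p`, `padj`.
#' @export
setEnrichment <- function(hits, universe, sets) {
    hits <- intersect(hits, universe)
    res <- lapply(names(sets), function(nm) {
        inSet <- intersect(sets[[nm]], universe)
        ov <- length(intersect(hits, inSet))
        p <- stats::phyper(ov - 1L, length(inSet),
                           length(universe) - length(inSet),
                           length(hits), lower.tail = FALSE)
        data.frame(set = nm, nSet = length(inSet), nOverlap = ov, p = p)
    })
    out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out
}
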