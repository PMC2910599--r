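# Independent brute-force oracles used to check the package's exact
# statistics and algorithms on small inputs.

# Exact 3x2 Fisher p by enumeration over complete tables, using the
# factorial form of the conditional probability (independent of the
# lchoose-based implementation route).
enumFisher3x2 <- function(tab) {
    r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
    logConst <- sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(N)
    probs <- c(); pObs <- NA
    for (a in 0:r[1]) for (b in 0:r[2]) {
        d <- cs[1] - a - b
        if (d < 0 || d > r[3]) next
        cells <- c(a, r[1] - a, b, r[2] - b, d, r[3] - d)
        lp <- logConst - sum(lfactorial(cells))
        probs <- c(probs, exp(lp))
        if (a == tab[1, 1] && b == tab[2, 1]) pObs <- exp(lp)
    }
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# One-tailed Mann-Whitney p for "x greater than y" by enumerating every
# assignment of the pooled values into the two groups (tie-free inputs).
permMWUGreater <- function(x, y) {
    pool <- c(x, y); nx <- length(x)
    uObs <- sum(outer(x, y, ">"))
    splits <- utils::combn(length(pool), nx)
    us <- apply(splits, 2L, function(ix)
        sum(outer(pool[ix], pool[-ix], ">")))
    mean(us >= uObs)
}

# One-tailed Spearman p for positive correlation by enumerating all n!
# permutations of y (tie-free inputs).
permSpearmanGreater <- function(x, y) {
    rhoObs <- stats::cor(x, y, method = "spearman")
    perms <- .allPerms(length(y))
    rhos <- apply(perms, 1L, function(p)
        stats::cor(x, y[p], method = "spearman"))
    mean(rhos >= rhoObs - 1e-12)
}

.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- .allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, sub + (sub >= i))))
}

# Exhaustive penalised segmentation: minimal SSE + penalty * k over all
# breakpoint placements with k <= maxBk.
bruteSegment <- function(x, penalty, maxBk) {
    n <- length(x)
    best <- list(obj = Inf, bk = integer(0))
    for (k in 0:min(maxBk, n - 1L)) {
        combs <- if (k == 0L) list(integer(0)) else
            asplit(utils::combn(n - 1L, k), 2L)
        for (bk in combs) {
            bounds <- c(0L, bk, n)
            sse <- 0
            for (i in seq_len(length(bounds) - 1L)) {
                seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
                sse <- sse + sum((seg - mean(seg))^2)
            }
            obj <- sse + penalty * k
            if (obj < best$obj - 1e-12) best <- list(obj = obj, bk = bk)
        }
    }
    best
}

# Brute-force scan for maximal runs of consecutive non-missing values
# strictly above a threshold, of minimal length minLen.
bruteRuns <- function(v, thr, minLen) {
    qual <- !is.na(v) & v > thr
    runs <- list()
    i <- 1L
    while (i <= length(v)) {
        if (qual[i]) {
            j <- i
            while (j < length(v) && qual[j + 1L]) j <- j + 1L
            if (j - i + 1L >= minLen)
                runs[[length(runs) + 1L]] <- c(start = i, end = j)
            i <- j + 1L
        } else i <- i + 1L
    }
    runs
}

# Minimal AcghProfile with given combined log2 values (zero replicate SD,
# passing SNR), clones every 100 kb on one chromosome.
makeProfile <- function(values, sampleName = "s1", missing = NULL,
                        chrom = "chr8", spacingBp = 1e5,
                        lengthBp = 1e5) {
    n <- length(values)
    starts <- (seq_len(n) - 1L) * spacingBp
    p <- AcghProfile(sampleName = sampleName,
                     cloneId = sprintf("c%03d", seq_len(n)),
                     chrom = rep(chrom, n), start = starts,
                     end = starts + lengthBp,
                     replicates = cbind(values, values, values),
                     snr = rep(10, n))
    if (!is.null(missing)) {
        p@missing[missing] <- TRUE
        p@log2Ratio[missing] <- NA_real_
    }
    p
}

# StateMatrix straight from a clones x samples integer matrix.
makeStateMatrix <- function(st, cohorts, spacingBp = 1e6) {
    n <- nrow(st)
    if (is.null(colnames(st)))
        colnames(st) <- sprintf("s%02d", seq_len(ncol(st)))
    starts <- (seq_len(n) - 1L) * spacingBp
    new("StateMatrix", states = st,
        clones = lineamp:::.bpGRanges("chr8", starts, starts + spacingBp,
                                      sprintf("c%03d", seq_len(n))),
        cohorts = as.factor(cohorts),
        observed = !is.na(st))
}
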