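# Expression statistics and dosage integration.

test_that("one-tailed differential expression gives exact small-sample p-values", {
    ex <- rbind(p1 = c(1, 2, 3, 4, 5, 6),
                p2 = c(5, 6, 4, 1, 3, 2))
    panel <- ExpressionPanel(
        ex,
        data.frame(probeId = c("p1", "p2"), gene = c("g1", "g2"),
                   chrom = "chr8", start = c(0, 100), end = c(50, 200)),
        cohorts = rep(c("A", "B"), each = 3))
    de <- diffExpression(panel, "A", "B")
    expect_equal(de$p[de$probeId == "p1"], 0.05)  # 1 / choose(6, 3)
    expect_true(de$p[de$probeId == "p2"] >= 0.5)
    # a probe constant across all samples is flagged with p = 1
    ex2 <- rbind(ex, p3 = rep(2, 6))
    panel2 <- ExpressionPanel(
        ex2,
        data.frame(probeId = c("p1", "p2", "p3"),
                   gene = c("g1", "g2", "g3"), chrom = "chr8",
                   start = c(0, 100, 300), end = c(50, 200, 400)),
        cohorts = rep(c("A", "B"), each = 3))
    de2 <- diffExpression(panel2, "A", "B")
    expect_true(de2$constant[3] && de2$p[3] == 1)
    expect_true(all(de2$padj >= de2$p))
})

test_that("exact MWU p-values equal full label enumeration", {
    set.seed(21)
    for (sizes in list(c(3, 3), c(4, 4), c(5, 5), c(3, 7), c(4, 6))) {
        x <- sample(seq_len(40), sizes[1])
        y <- sample(setdiff(seq_len(40), x), sizes[2])
        p <- suppressWarnings(
            stats::wilcox.test(x, y, alternative = "greater")$p.value)
        expect_equal(p, permMWUGreater(x, y), tolerance = 1e-12)
    }
})

test_that("probe collapse picks lowest p or highest intensity per gene", {
    res <- data.frame(probeId = c("a", "b", "c", "d"),
                      gene = c("g1", "g1", "g2", "g3"),
                      p = c(0.03, 0.001, 0.2, 0.5),
                      meanIntensity = c(5.1, 7.9, 3.0, 1.0))
    byP <- collapseProbes(res, "min_p")
    expect_identical(byP$probeId[byP$gene == "g1"], "b")
    expect_equal(nrow(byP), 3L)
    byI <- collapseProbes(res, "max_intensity")
    expect_identical(byI$probeId[byI$gene == "g1"], "b")
    # single-probe genes pass through unchanged
    expect_identical(byP[byP$gene == "g3", "probeId"], "d")
    expect_error(collapseProbes(res, "other"))
})

test_that("windowed Z-scores standardise to mean 0, SD 1 and honour segments", {
    # clones exactly tile 10-kb windows; step profile
    vals <- c(rep(0, 10), rep(1, 10))
    starts <- (seq_along(vals) - 1L) * 1e4
    p <- AcghProfile("s", sprintf("c%02d", seq_along(vals)),
                     rep("chr8", 20), starts, starts + 1e4,
                     replicates = cbind(vals, vals), snr = rep(10, 20))
    w <- windowedZscore(p, windowBp = 1e4)
    expect_equal(mean(w$z), 0, tolerance = 1e-10)
    expect_equal(stats::sd(w$z), 1, tolerance = 1e-10)
    # a window fully inside one segment carries that segment's value
    expect_equal(w$value[3], 0)
    expect_equal(w$value[15], 1)
    # constant profile: flagged, Z undefined
    pc <- makeProfile(rep(0.2, 10))
    wc <- windowedZscore(pc)
    expect_true(attr(wc, "zeroVariance"))
    expect_true(all(is.na(wc$z)))
})

test_that("Spearman dosage correlation matches known values and enumeration", {
    expect_equal(dosageCorrelation(1:5, c(2, 4, 5, 7, 9))$rho, 1)
    expect_equal(dosageCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
    expect_error(dosageCorrelation(1:3, 1:3), "at least 4")
    set.seed(31)
    for (n in 5:7) {
        x <- sample(100, n); y <- sample(100, n)
        got <- dosageCorrelation(x, y)
        expect_equal(got$p, permSpearmanGreater(x, y), tolerance = 1e-12)
    }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
    set.seed(17)
    x <- rnorm(20); y <- rnorm(20)
    r0 <- dosageCorrelation(x, y)$rho
    expect_equal(dosageCorrelation(exp(x), y)$rho, r0)
    expect_equal(dosageCorrelation(x, y^3 + 2 * y)$rho, r0)
})

test_that("null dosage correlations reject at most at the nominal rate", {
    set.seed(99)
    ps <- replicate(600, dosageCorrelation(rnorm(20), rnorm(20))$p)
    rate <- mean(ps < 0.05)
    # binomial 3-sigma envelope around 0.05
    expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("estimated dosage correlation grows with the coupling slope", {
    set.seed(55)
    meanRho <- vapply(c(0, 0.5, 1), function(slope) {
        mean(replicate(40, {
            z <- rnorm(15)
            e <- slope * z + rnorm(15, sd = 0.5)
            dosageCorrelation(z, e)$rho
        }))
    }, numeric(1))
    expect_true(all(diff(meanRho) > 0))
})

test_that("gain-versus-neutral test excludes losses and applies guards", {
    r <- dosageGroupTest(c(10, 11, 12, 1, 2, 3),
                         c(1L, 1L, 1L, 0L, 0L, 0L))
    expect_true(r$testable)
    expect_equal(r$p, 0.05)
    expect_true(r$medianHigher && r$meanHigher)
    # loss samples are excluded and counted
    r2 <- dosageGroupTest(c(10, 11, 1, 2, -5, -6),
                          c(1L, 1L, 0L, 0L, -1L, -1L))
    expect_equal(r2$nLossExcluded, 2L)
    expect_equal(r2$nGain + r2$nNeutral, 4L)
    # empty gain group: not testable, no error
    r3 <- dosageGroupTest(c(1, 2, 3), c(0L, 0L, 0L))
    expect_false(r3$testable)
    expect_true(is.na(r3$p))
    # a gain group with the lower median fails the guard
    r4 <- dosageGroupTest(c(1, 2, 3, 10, 11, 12),
                          c(1L, 1L, 1L, 0L, 0L, 0L))
    expect_false(r4$medianHigher)
})

test_that("tumor-versus-normal fold uses linear-scale medians", {
    r <- tumorVsNormal(c(7, 8, 9), c(1, 2, 3), scale = "linear")
    expect_equal(r$fold, 4)
    # log10 inputs are exponentiated first
    r2 <- tumorVsNormal(log10(c(7, 8, 9)), log10(c(1, 2, 3)),
                        scale = "log10")
    expect_equal(r2$fold, 4)
    # identical distributions: fold 1, one-tailed p at least 0.5
    r3 <- tumorVsNormal(c(1, 2, 3), c(1, 2, 3), scale = "linear")
    expect_equal(r3$fold, 1)
    expect_gte(r3$p, 0.5)
    # non-positive linear median: flagged undefined
    r4 <- tumorVsNormal(c(-1, -2, -3), c(1, 2, 3), scale = "linear")
    expect_false(r4$foldDefined)
    expect_true(is.na(r4$fold))
})
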