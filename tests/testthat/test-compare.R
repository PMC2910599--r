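# Cohort disparity machinery: imputation, region aggregation, the exact
# 3x2 Fisher test and the full comparison pipeline.

test_that("imputation fills from the nearest observed neighbour within the window", {
    # clones 1 Mb apart; sample 1: missing clone flanked by +1 at 1 Mb
    st <- matrix(c(1L, NA, 1L,
                   NA, 0L, 0L), ncol = 2)
    m <- makeStateMatrix(st, c("A", "A"))
    im <- states(imputeMissingStates(m, windowBp = 1e7))
    expect_identical(unname(im[2, 1]), 1L)
    # nearest-wins: +1 at 2 Mb beats -1 at 5 Mb
    st2 <- matrix(c(NA, NA, 1L, NA, NA, NA, -1L), ncol = 1)
    m2 <- makeStateMatrix(st2, "A")
    expect_identical(unname(states(imputeMissingStates(m2, 1e7))[1, 1]), 1L)
    # exact distance tie with disagreeing states -> neutral
    st3 <- matrix(c(1L, NA, -1L), ncol = 1)
    expect_identical(
        unname(states(imputeMissingStates(makeStateMatrix(st3, "A"), 1e7))[2, 1]),
        0L)
})

test_that("imputation respects the 10 Mb window and never alters observations", {
    # neighbours at 12 Mb on both sides stay out of reach
    st <- matrix(c(1L, rep(NA, 23L), 1L), ncol = 1)
    m <- makeStateMatrix(st, "A", spacingBp = 1e6)  # midpoints 1 Mb apart
    im <- imputeMissingStates(m, windowBp = 1e7)
    expect_true(is.na(states(im)[13, 1]))  # 12 Mb from both ends
    expect_false(is.na(states(im)[5, 1]))
    expect_identical(states(im)[c(1, 25), 1], c(1L, 1L))
})

test_that("imputation is idempotent even through chains of missing clones", {
    set.seed(5)
    st <- matrix(sample(c(1L, 0L, -1L, NA), 200, replace = TRUE,
                        prob = c(0.2, 0.4, 0.2, 0.2)), ncol = 4)
    m <- makeStateMatrix(st, rep("A", 4), spacingBp = 4e6)
    once <- imputeMissingStates(m, 1e7)
    twice <- imputeMissingStates(once, 1e7)
    expect_identical(states(once), states(twice))
    obs <- !is.na(st)
    expect_identical(states(once)[obs], st[obs])
})

test_that("region aggregation splits where adjacent agreement drops below 90%", {
    # all samples identical everywhere -> one region
    st <- matrix(rep(c(0L, 0L, 1L, 1L), 10), ncol = 10)
    m <- makeStateMatrix(st, rep("A", 10))
    expect_identical(aggregateRegions(m, "A", similarity = 1),
                     c(1L, 1L, 2L, 2L))
    # adjacent pair agreeing in 8/10 samples -> boundary (0.8 < 0.9)
    st2 <- matrix(0L, nrow = 2, ncol = 10)
    st2[2, 1:2] <- 1L
    m2 <- makeStateMatrix(st2, rep("A", 10))
    expect_identical(aggregateRegions(m2, "A", 0.9), c(1L, 2L))
    # 9/10 agreement stays together
    st3 <- matrix(0L, nrow = 2, ncol = 10)
    st3[2, 1] <- 1L
    expect_identical(aggregateRegions(makeStateMatrix(st3, rep("A", 10)),
                                      "A", 0.9), c(1L, 1L))
})

test_that("region aggregation equals a left-to-right pairwise scan", {
    set.seed(8)
    for (i in 1:25) {
        nc <- sample(3:12, 1); ns <- sample(2:8, 1)
        st <- matrix(sample(c(-1L, 0L, 1L, NA), nc * ns, replace = TRUE,
                            prob = c(0.2, 0.4, 0.3, 0.1)), nc, ns)
        m <- makeStateMatrix(st, rep("A", ns))
        got <- aggregateRegions(m, "A", 0.9)
        expected <- 1L
        for (k in 2:nc) {
            agree <- st[k - 1, ] == st[k, ]
            den <- sum(!is.na(agree))
            sim <- if (den == 0) 1 else sum(agree, na.rm = TRUE) / den
            expected <- c(expected,
                          expected[k - 1] + as.integer(sim < 0.9))
        }
        expect_identical(got, expected)
    }
})

test_that("fisher3x2 reproduces hand-enumerable cases", {
    expect_equal(fisher3x2(matrix(c(2, 0, 0, 0, 0, 2), 3, 2)), 1 / 3,
                 tolerance = 1e-12)
    # identical columns: no association, p = 1
    expect_equal(fisher3x2(matrix(c(3, 2, 1, 3, 2, 1), 3, 2)), 1,
                 tolerance = 1e-12)
    expect_error(fisher3x2(matrix(0, 3, 2)), "zero grand total")
})

test_that("fisher3x2 matches the enumeration oracle and fisher.test", {
    set.seed(12)
    for (i in 1:40) {
        tab <- matrix(sample(0:4, 6, replace = TRUE), 3, 2)
        if (sum(tab) == 0) tab[1, 1] <- 1
        p <- fisher3x2(tab)
        expect_equal(p, enumFisher3x2(tab), tolerance = 1e-12)
        # column exchange symmetry
        expect_equal(p, fisher3x2(tab[, 2:1]), tolerance = 1e-12)
        # independent cross-check against stats::fisher.test
        if (all(rowSums(tab) > 0))
            expect_equal(p, stats::fisher.test(tab)$p.value,
                         tolerance = 1e-6)
    }
})

test_that("compareCohorts reports a planted difference with exact frequencies", {
    # 30 clones; clones 10-14 gained in 40% of B, never in A; noise-free
    nA <- 50L; nB <- 50L
    st <- matrix(0L, nrow = 30, ncol = nA + nB)
    carriers <- nA + seq_len(20L)
    st[10:14, carriers] <- 1L
    m <- makeStateMatrix(st, rep(c("A", "B"), c(nA, nB)))
    reg <- compareCohorts(m, "A", "B")
    expect_equal(nrow(reg), 1L)
    expect_equal(reg$direction, "gain")
    expect_equal(reg$higherCohort, "B")
    expect_equal(reg$freqA, 0)
    expect_equal(reg$freqB, 0.40)
    expect_equal(reg$startIndex, 10L)
    expect_equal(reg$endIndex, 14L)
    # BH audit trail: adjusted >= raw, monotone in raw order
    audit <- attr(reg, "audit")
    ok <- !is.na(audit$p)
    expect_true(all(audit$padj[ok] >= audit$p[ok]))
    o <- order(audit$p[ok])
    expect_true(all(diff(audit$padj[ok][o]) >= -1e-12))
})

test_that("the >20% group frequency filter removes weakly altered regions", {
    nA <- 50L; nB <- 50L
    st <- matrix(0L, nrow = 30, ncol = nA + nB)
    # 15% of B gained: significant perhaps, but below the frequency bar
    st[10:14, nA + seq_len(8L)] <- 1L
    m <- makeStateMatrix(st, rep(c("A", "B"), c(nA, nB)))
    reg <- compareCohorts(m, "A", "B", minGroupFrequency = 0.20)
    expect_equal(nrow(reg), 0L)
})

test_that("degenerate all-neutral cohorts give an empty result, not an error", {
    st <- matrix(0L, nrow = 10, ncol = 8)
    m <- makeStateMatrix(st, rep(c("A", "B"), each = 4))
    reg <- compareCohorts(m, "A", "B")
    expect_s3_class(reg, "data.frame")
    expect_equal(nrow(reg), 0L)
})

test_that("adjacent concordant significant regions merge within 1 Mb", {
    nA <- 40L; nB <- 40L
    st <- matrix(0L, nrow = 12, ncol = nA + nB)
    carriers <- nA + seq_len(20L)
    st[3:5, carriers] <- 1L
    st[7:9, carriers] <- 1L  # gap of one clone = 1 Mb grid spacing
    m <- makeStateMatrix(st, rep(c("A", "B"), c(nA, nB)), spacingBp = 1e6)
    reg <- compareCohorts(m, "A", "B", mergeGapBp = 2e6)
    expect_equal(nrow(reg), 1L)
    expect_equal(reg$startIndex, 3L)
    expect_equal(reg$endIndex, 9L)
    # without merging they stay separate
    reg2 <- compareCohorts(m, "A", "B", mergeGapBp = 1e5)
    expect_equal(nrow(reg2), 2L)
})

test_that("alteration frequencies count gains and losses per informative sample", {
    st <- matrix(c(rep(1L, 4), rep(0L, 5), NA,
                   rep(-1L, 2), rep(0L, 8)), ncol = 10, byrow = TRUE)
    m <- makeStateMatrix(st, rep("A", 10))
    fr <- alterationFrequency(m, "A")
    expect_equal(fr$gainFreq[1], 4 / 9)
    expect_equal(fr$lossFreq[2], 0.2)
    # all-missing clone: NaN flagged, not zero
    st2 <- matrix(NA_integer_, 1, 3)
    fr2 <- alterationFrequency(makeStateMatrix(st2, rep("A", 3)), "A")
    expect_true(is.nan(fr2$gainFreq[1]))
    expect_equal(fr2$nInformative[1], 0)
    expect_error(alterationFrequency(m, "B"), "empty cohort")
})
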