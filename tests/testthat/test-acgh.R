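# Per-sample aCGH processing: QC, segmentation, state calling,
# amplification detection and group scoring.

test_that("replicate QC removes high-SD and low-SNR clones and keeps the rest", {
    p <- makeProfile(c(0.1, 0.2, 0.3))
    p@replicateSD <- c(0.08, 0.05, 0.05)
    p@snr <- c(10, 2.9, 5)
    f <- qcFilter(p)
    expect_identical(isMissing(f), c(TRUE, TRUE, FALSE))
    expect_true(is.na(log2Ratios(f)[1]) && is.na(log2Ratios(f)[2]))
    expect_equal(log2Ratios(f)[3], 0.3)
    rep <- qcReport(f)
    expect_equal(rep$nRemoved + rep$nRetained, rep$nInput)
    expect_equal(rep$nRemoved, 2L)
    # boundary values are retained (thresholds are strict)
    p2 <- makeProfile(c(0, 0))
    p2@replicateSD <- c(0.075, 0.01); p2@snr <- c(5, 3)
    expect_identical(isMissing(qcFilter(p2)), c(FALSE, FALSE))
})

test_that("QC raises an explicit error when every clone is removed", {
    p <- makeProfile(c(0.1, 0.2))
    p@snr <- c(1, 2)
    expect_error(qcFilter(p), "empty profile")
})

test_that("segmentation recovers exact two-level and constant signals", {
    fit <- segmentLog2(c(0, 0, 0, 1, 1, 1), penalty = 0.1,
                       maxBreakpoints = 5)
    expect_equal(nrow(fit), 2L)
    expect_equal(fit$mean, c(0, 1))
    expect_equal(fit$endIndex, c(3L, 6L))
    fit1 <- segmentLog2(rep(0.3, 8), penalty = 0.1, maxBreakpoints = 5)
    expect_equal(nrow(fit1), 1L)
    expect_equal(fit1$mean, 0.3)
})

test_that("segmentation matches exhaustive breakpoint search on small inputs", {
    set.seed(42)
    for (i in 1:40) {
        n <- sample(5:12, 1)
        x <- rnorm(n)
        pen <- runif(1, 0.02, 2)
        mk <- sample(0:3, 1)
        fit <- segmentLog2(x, pen, mk)
        oracle <- bruteSegment(x, pen, mk)
        expect_equal(attr(fit, "objective"), oracle$obj, tolerance = 1e-9)
        expect_identical(as.integer(fit$endIndex[-nrow(fit)]),
                         as.integer(oracle$bk))
    }
})

test_that("unpenalised segmentation SSE is non-increasing in the breakpoint cap", {
    set.seed(7)
    x <- rnorm(15)
    sse <- vapply(0:6, function(k)
        attr(segmentLog2(x, 0, k), "objective"), numeric(1))
    expect_true(all(diff(sse) <= 1e-12))
})

test_that("state calling assigns segment states per clone, NA for missing", {
    p <- makeProfile(c(0, 0, 0.5, 0.5, 0.5, 0, -0.4, -0.4),
                     missing = 6L)
    sp <- segmentProfile(p, penaltyLambda = 1)
    st <- callStates(sp)
    expect_length(st, 8L)
    expect_identical(st[3:5], rep(1L, 3))
    expect_identical(st[7:8], rep(-1L, 2))
    expect_true(is.na(st[6]))
    expect_identical(st[1:2], rep(0L, 2))
    # a neutral profile gives an all-zero state vector
    stNull <- callStates(segmentProfile(makeProfile(rep(0.01, 6))))
    expect_identical(stNull, rep(0L, 6L))
})

test_that("segment table partitions the clone range contiguously", {
    set.seed(11)
    p <- makeProfile(rnorm(30, sd = 0.1), missing = c(4L, 19L))
    sg <- segmentTable(segmentProfile(p))
    expect_equal(sg$startIndex[1], 1L)
    expect_equal(sg$endIndex[nrow(sg)], 30L)
    if (nrow(sg) > 1)
        expect_true(all(sg$startIndex[-1] == sg$endIndex[-nrow(sg)] + 1L))
})

test_that("amplification detection keeps only runs of >= 2 consecutive clones", {
    p <- makeProfile(c(0.1, 0.7, 0.65, 0.2, 0.9))
    amp <- detectAmplifications(p, threshold = 0.6, minConsecutive = 2)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$startIndex, 2L)
    expect_equal(amp$endIndex, 3L)
    expect_equal(detectAmplifications(makeProfile(c(0.1, 0.5, 0.6)),
                                      0.6, 2) |> nrow(), 0L)
})

test_that("amplification detection equals the brute-force run scanner", {
    set.seed(3)
    for (i in 1:60) {
        n <- sample(3:20, 1)
        v <- round(rnorm(n, 0.4, 0.4), 2)
        miss <- if (runif(1) < 0.5) sample(n, sample(0:2, 1)) else integer(0)
        p <- makeProfile(v, missing = if (length(miss)) miss else NULL)
        amp <- detectAmplifications(p, 0.6, 2)
        oracle <- bruteRuns(log2Ratios(p), 0.6, 2)
        expect_equal(nrow(amp), length(oracle))
        if (length(oracle)) {
            expect_identical(amp$startIndex,
                             vapply(oracle, `[[`, 1L, "start"))
            expect_identical(amp$endIndex,
                             vapply(oracle, `[[`, 1L, "end"))
        }
        # idempotence on the same profile
        expect_identical(amp, detectAmplifications(p, 0.6, 2))
    }
})

test_that("a stricter amplification threshold yields a clone-wise subset", {
    set.seed(9)
    for (i in 1:20) {
        p <- makeProfile(round(rnorm(25, 0.5, 0.4), 2))
        cov <- function(amp) {
            out <- logical(25)
            for (j in seq_len(nrow(amp)))
                out[amp$startIndex[j]:amp$endIndex[j]] <- TRUE
            out
        }
        expect_true(all(cov(detectAmplifications(p, 0.8, 2)) <=
                        cov(detectAmplifications(p, 0.6, 2))))
    }
})

test_that("group amplification score counts covering samples per clone", {
    vals <- rep(0, 10)
    hot <- replace(vals, 4:6, 1)
    profiles <- c(
        lapply(1:7, function(i) makeProfile(hot, sprintf("a%02d", i))),
        lapply(8:20, function(i) makeProfile(vals, sprintf("a%02d", i))))
    sc <- amplificationScore(profiles, threshold = 0.6)
    expect_equal(sc$fraction[5], 0.35)
    expect_equal(sc$count[1], 0L)
    expect_equal(sum(sc$count), 7L * 3L)
    # all-quiet group gives an all-zero score
    sc0 <- amplificationScore(profiles[8:10])
    expect_true(all(sc0$count == 0L))
    # inconsistent grids are rejected
    bad <- makeProfile(vals[1:9])
    expect_error(amplificationScore(c(profiles[1:2], list(bad))),
                 "inconsistent clone grids")
})
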