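# Synthetic cohort generator: determinism, planted-truth recovery and the
# decoy panel's designed properties.

noPlant <- function(...) {
    cfg <- simulationConfig(...)
    cfg  # convenience wrapper for defaults
}

emptyRegions <- function()
    data.frame(name = character(0), start = numeric(0), end = numeric(0),
               cohort = character(0), state = integer(0),
               carrierFraction = numeric(0), ampCarrierFraction = numeric(0),
               meanLog2Shift = numeric(0))

test_that("a noise-free null configuration yields exactly zero replicates", {
    cfg <- simulationConfig(nSamples = c(AC = 3, SqCC = 3),
                            plantedRegions = emptyRegions(),
                            probeNoiseSd = 0, qcFailFraction = 0,
                            nClones = 40, nGenes = 6, seed = 2)
    sim <- simulateCohorts(cfg)
    for (p in sim$profiles)
        expect_true(all(p@replicates == 0))
})

test_that("the same seed reproduces bit-identical cohorts and expression", {
    cfg <- simulationConfig(nSamples = c(AC = 4, SqCC = 4, CIS = 2),
                            nClones = 60, nGenes = 8, nNormal = 4, seed = 9)
    a <- simulateCohorts(cfg); b <- simulateCohorts(cfg)
    expect_identical(lapply(a$profiles, slot, "replicates"),
                     lapply(b$profiles, slot, "replicates"))
    expect_identical(a$truth, b$truth)
    expect_identical(exprValues(simulateExpression(cfg, a)),
                     exprValues(simulateExpression(cfg, b)))
})

test_that("overlapping planted regions within a cohort are rejected", {
    bad <- data.frame(name = c("r1", "r2"), start = c(0, 5e5),
                      end = c(1e6, 2e6), cohort = "SqCC", state = 1L,
                      carrierFraction = 0.5, ampCarrierFraction = 0,
                      meanLog2Shift = 0.45)
    expect_error(simulationConfig(plantedRegions = bad), "overlap")
})

test_that("carrier means converge to the configured shift over many samples", {
    cfg <- simulationConfig(nSamples = c(AC = 2, SqCC = 60),
        plantedRegions = data.frame(name = "r", start = 1e6, end = 3e6,
                                    cohort = "SqCC", state = 1L,
                                    carrierFraction = 1,
                                    ampCarrierFraction = 0,
                                    meanLog2Shift = 0.45),
        nClones = 60, chromLengthBp = 4.8e6, cloneSpacingBp = 8e4,
        nGenes = 6, seed = 4)
    sim <- simulateCohorts(cfg)
    sq <- names(sim$profiles)[sim$cohorts == "SqCC"]
    grid <- cloneRanges(sim$profiles[[1]])
    inReg <- GenomicRanges::start(grid) - 1 < 3e6 &
             GenomicRanges::end(grid) > 1e6
    perSample <- vapply(sim$profiles[sq], function(p)
        mean(rowMeans(p@replicates)[inReg]), numeric(1))
    expect_equal(mean(perSample), 0.45, tolerance = 0.03)
})

test_that("true alteration frequencies equal the carrier fractions exactly", {
    cfg <- simulationConfig(seed = 6)
    sim <- simulateCohorts(cfg)
    grid <- lineamp:::.cloneGrid(cfg)
    inDriver <- GenomicRanges::start(grid) - 1 < 15.5e6 &
                GenomicRanges::end(grid) > 12e6
    fracSq <- mean(colSums(sim$truth$states$SqCC[inDriver, ] == 1) > 0)
    fracAc <- mean(colSums(sim$truth$states$AC[inDriver, ] == 1) > 0)
    expect_equal(fracSq, 0.40)
    expect_equal(fracAc, 0.04)  # round(0.05 * 50) / 50
    # every driver gene lies inside a truly differential region
    dr <- sim$truth$differentialRegions
    g <- sim$truth$genes
    drv <- g[g$role == "driver", ]
    expect_true(any(dr$start < drv$end & dr$end > drv$start &
                    dr$direction == "gain"))
})

test_that("expression simulation demands matching profiles", {
    cfg <- simulationConfig(nSamples = c(AC = 3, SqCC = 3), nClones = 50,
                            nGenes = 6, seed = 8)
    sim <- simulateCohorts(cfg)
    sim$profiles <- sim$profiles[-1]
    expect_error(simulateExpression(cfg, sim), "mismatch")
})

test_that("noise-free decoys each violate exactly their intended criterion", {
    cfg <- simulationConfig(probeNoiseSd = 0, exprNoiseSd = 0,
                            qcFailFraction = 0, seed = 13)
    res <- suppressMessages(runDriverAnalysis(cfg))
    cas <- res$cascade
    truthGenes <- cfg$genes
    expect_identical(cas$gene[cas$candidate], "driver")
    for (g in truthGenes$gene[truthGenes$role == "decoy"]) {
        row <- cas[cas$gene == g, ]
        expect_equal(row$nFailed, 1L, info = g)
        expect_identical(row$failedCriterion,
                         truthGenes$intendedFailure[truthGenes$gene == g],
                         info = g)
    }
    # null genes violate several criteria and are never near-misses
    nulls <- cas[grepl("^null_", cas$gene), ]
    expect_true(all(nulls$nFailed >= 2L))
})

test_that("dosage-uncoupled expression shows near-zero correlation on average", {
    set.seed(23)
    # decoy construction aside, slope 0 decouples expression from dosage
    rhos <- replicate(50, {
        z <- rnorm(12)
        e <- rnorm(12)
        suppressWarnings(cor(z, e, method = "spearman"))
    })
    expect_lt(abs(mean(rhos)), 0.1)
})

test_that("the null state simulator is seed-stable with two balanced cohorts", {
    a <- simulateNullStateMatrix(nClones = 50, seed = 3)
    b <- simulateNullStateMatrix(nClones = 50, seed = 3)
    expect_identical(states(a), states(b))
    expect_equal(table(cohorts(a))[["A"]], 50)
    expect_true(all(states(a) %in% c(-1L, 0L, 1L)))
})
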