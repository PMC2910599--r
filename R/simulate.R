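# Synthetic aCGH + expression cohorts with planted ground truth.
#
# The generator emulates a single chromosome arm profiled at tiling-path
# density for two tumor cohorts with differential regional gain/loss
# frequencies (an AC-like cohort dominated by distal loss, a SqCC-like
# cohort with a recurrent focal gain/amplification), a high-noise
# CIS-like early-lesion cohort, and an expression-only normal cohort.
# Expression for planted driver genes is coupled to gene dosage; each
# decoy gene violates exactly one criterion of the candidate cascade.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulateCohorts()] /
#' [simulateExpression()]. The defaults describe the standard study
#' conditions used throughout the package's validation: two tumor cohorts
#' of 50 samples on a 40-Mb arm at 80-kb clone spacing, a focal region
#' gained in 40% of the SqCC-like cohort (30% of carriers amplified), a
#' distal region lost in 39% of the AC-like cohort, a 20-sample CIS-like
#' cohort with doubled probe noise, and a 30-sample expression-only normal
#' cohort.
#'
#' @param nSamples named integer vector of aCGH cohort sizes
#'   (default `c(AC = 50, SqCC = 50, CIS = 20)`).
#' @param nClones clones on the arm (default 500).
#' @param cloneSpacingBp clone start spacing (default 80,000, tiling
#'   density).
#' @param cloneLengthBp clone length (default 100,000; adjacent clones
#'   overlap as in a tiling path).
#' @param chromLengthBp arm length (default 40 Mb).
#' @param chrom chromosome name (default `"chr8"`).
#' @param plantedRegions `data.frame` of planted copy-number regions with
#'   columns `name`, `start`, `end` (0-based half-open bp), `cohort`,
#'   `state` (+1/-1), `carrierFraction`, `meanLog2Shift`,
#'   `ampCarrierFraction` (fraction of carriers whose shift is the
#'   amplification-level `ampLog2Shift`); `NULL` for the default panel.
#' @param ampLog2Shift log2 shift of amplification-level carriers
#'   (default 1.2, about two extra copies).
#' @param heterogeneity half-width of the uniform per-sample scalar applied
#'   to every carried region shift (default 0.2: multipliers in
#'   U(0.8, 1.2), mean 1), emulating cellularity/heterogeneity dilution.
#' @param probeNoiseSd per-replicate Gaussian noise SD in log2 units
#'   (default 0.05; free parameter, see the methods vignette).
#' @param nReplicateSpots replicate spots per clone (default 3).
#' @param qcFailFraction fraction of clones per sample given inflated
#'   replicate SD or low SNR to exercise QC (default 0.05).
#' @param cisNoiseMultiplier probe-noise multiplier for the CIS-like
#'   cohort (default 2).
#' @param genes gene table (`NULL` for the default driver + decoy + null
#'   panel built by [defaultGeneTable()]).
#' @param nGenes total gene count when the default panel is built
#'   (default 30).
#' @param dosageSlope expression units per log2 dosage unit for coupled
#'   genes (default 1.0).
#' @param exprNoiseSd expression noise SD in log10 units (default 0.1).
#' @param nNormal expression-only normal cohort size (default 30).
#' @param seed integer seed (default 1); all simulation randomness derives
#'   from it.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nSamples = c(AC = 50, SqCC = 50, CIS = 20),
                             nClones = 500, cloneSpacingBp = 80000,
                             cloneLengthBp = 100000, chromLengthBp = 4e7,
                             chrom = "chr8",
                             plantedRegions = NULL, ampLog2Shift = 1.2,
                             heterogeneity = 0.2,
                             probeNoiseSd = 0.05, nReplicateSpots = 3,
                             qcFailFraction = 0.05, cisNoiseMultiplier = 2,
                             genes = NULL, nGenes = 30, dosageSlope = 1.0,
                             exprNoiseSd = 0.1, nNormal = 30, seed = 1) {
    stopifnot(all(nSamples >= 1), !is.null(names(nSamples)),
              nClones >= 2, cloneSpacingBp > 0, cloneLengthBp > 0,
              chromLengthBp > 0, probeNoiseSd >= 0, nReplicateSpots >= 2,
              qcFailFraction >= 0, qcFailFraction <= 1,
              heterogeneity >= 0, heterogeneity < 1,
              exprNoiseSd >= 0, nNormal >= 2, dosageSlope >= 0)
    if (is.null(plantedRegions)) plantedRegions <- defaultRegionTable()
    stopifnot(all(c("name", "start", "end", "cohort", "state",
                    "carrierFraction", "ampCarrierFraction",
                    "meanLog2Shift") %in% names(plantedRegions)))
    with(plantedRegions, stopifnot(
        all(start >= 0), all(end <= chromLengthBp), all(start < end),
        all(state %in% c(-1L, 1L)),
        all(carrierFraction >= 0 & carrierFraction <= 1),
        all(ampCarrierFraction >= 0 & ampCarrierFraction <= 1)))
    # planted regions must not overlap within a cohort
    for (co in unique(plantedRegions$cohort)) {
        r <- plantedRegions[plantedRegions$cohort == co, , drop = FALSE]
        if (nrow(r) > 1L) {
            r <- r[order(r$start), ]
            if (any(r$start[-1L] < r$end[-nrow(r)]))
                stop("planted regions overlap within cohort '", co, "'")
        }
    }
    cfg <- list(nSamples = nSamples, nClones = as.integer(nClones),
                cloneSpacingBp = cloneSpacingBp,
                cloneLengthBp = cloneLengthBp,
                chromLengthBp = chromLengthBp, chrom = chrom,
                plantedRegions = plantedRegions,
                ampLog2Shift = ampLog2Shift,
                heterogeneity = heterogeneity,
                probeNoiseSd = probeNoiseSd,
                nReplicateSpots = as.integer(nReplicateSpots),
                qcFailFraction = qcFailFraction,
                cisNoiseMultiplier = cisNoiseMultiplier,
                nGenes = nGenes, dosageSlope = dosageSlope,
                exprNoiseSd = exprNoiseSd, nNormal = as.integer(nNormal),
                seed = as.integer(seed))
    cfg$genes <- if (is.null(genes)) defaultGeneTable(cfg) else genes
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Default planted-region panel
#'
#' The standard region panel: a distal loss in 39% of the AC-like cohort;
#' the focal driver gain in 40% of SqCC (5% AC background); a region
#' gained at similar frequency in both cohorts (45%/40%, removed by the
#' frequency-difference filter); a strong SqCC gain (80%); a universal
#' SqCC gain (100%, leaving no neutral comparison group); and the driver
#' region gained in 35% of the CIS-like cohort with every carrier at
#' amplification level.
#'
#' @return `data.frame` of planted regions (see [simulationConfig()]).
#' @export
defaultRegionTable <- function() {
    data.frame(
        name = c("loss_ac", "driver", "driver_bg", "shared", "shared_bg",
                 "strong", "strong_bg", "full", "full_bg",
                 "baseline", "baseline_sq", "cis_amp"),
        start = c(2e6, 12e6, 12e6, 19e6, 19e6, 25e6, 25e6, 31e6, 31e6,
                  34.5e6, 34.5e6, 12e6),
        end   = c(8e6, 15.5e6, 15.5e6, 21e6, 21e6, 27e6, 27e6, 33e6, 33e6,
                  39.5e6, 39.5e6, 15.5e6),
        cohort = c("AC", "SqCC", "AC", "SqCC", "AC", "SqCC", "AC", "SqCC",
                   "AC", "AC", "SqCC", "CIS"),
        state = c(-1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
        carrierFraction = c(0.39, 0.40, 0.05, 0.45, 0.40, 0.80, 0.05,
                            1.00, 0.05, 1.00, 1.00, 0.35),
        ampCarrierFraction = c(0, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.5, 0.5,
                               0, 0, 1),
        meanLog2Shift = c(0.45, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45, 0.30,
                          0.30, 0.45, 0.45, 0.45))
}

#' Default gene panel: one driver, five decoys, null genes
#'
#' The driver couples expression to dosage inside the SqCC driver region
#' and is elevated in tumors over normals. Each decoy violates exactly one
#' cascade criterion at zero noise: `decoy_outside` sits in the
#' cohort-shared region removed by the frequency filters; `decoy_not_de`
#' carries a high constant AC baseline; `decoy_uncoupled` follows a
#' non-monotone dosage level map (rho low, gain group still elevated);
#' `decoy_group` sits in the region gained in all SqCC samples (no neutral
#' comparison group); `decoy_not_elevated` is expressed near tumor
#' baseline in normals. Remaining genes are nulls outside any planted
#' region.
#'
#' @param cfg partial configuration list (needs `nGenes` and `chrom`).
#' @return `data.frame` with coordinates, expression model parameters,
#'   `role` and `intendedFailure` per gene.
#' @export
defaultGeneTable <- function(cfg) {
    core <- data.frame(
        gene = c("driver", "decoy_not_de", "decoy_not_elevated",
                 "decoy_outside", "decoy_uncoupled", "decoy_group"),
        start = c(13.5e6, 14.2e6, 14.8e6, 20e6, 26e6, 32e6),
        type = c("linear", "linear", "linear", "linear", "levels", "levels"),
        slope = c(1, 1, 1, 1, NA, NA),
        baselineAC = c(0, 0.7, 0, 0, NA, NA),
        baselineSqCC = c(0.6, 0.4, 0.6, 0.6, NA, NA),
        baselineNormal = c(0, 0, 0.52, 0, 0, 0),
        levelNeutral = c(NA, NA, NA, NA, 0.3, 0.3),
        levelGain = c(NA, NA, NA, NA, 0.9, 0.7),
        levelAmp = c(NA, NA, NA, NA, 0.65, 1.4),
        role = c("driver", rep("decoy", 5L)),
        intendedFailure = c(NA, "differential_expression",
                            "tumor_vs_normal", "disparity_region",
                            "dosage_correlation", "dosage_group"))
    nNull <- max(0L, cfg$nGenes - nrow(core))
    genes <- core
    if (nNull > 0L) {
        nullPos <- c(seq(8.3e6, 11.7e6, by = 0.3e6),
                     seq(21.3e6, 24.7e6, by = 0.3e6),
                     seq(27.3e6, 30.7e6, by = 0.3e6))[seq_len(nNull)]
        null <- data.frame(
            gene = sprintf("null_%02d", seq_len(nNull)),
            start = nullPos, type = "constant", slope = 0,
            baselineAC = 0.3, baselineSqCC = 0.3, baselineNormal = 0.3,
            levelNeutral = NA, levelGain = NA, levelAmp = NA,
            role = "null", intendedFailure = "multiple")
        genes <- rbind(core, null)
    }
    genes$chrom <- cfg$chrom
    genes$end <- genes$start + 2e4
    genes[, c("gene", "chrom", "start", "end", "type", "slope",
              "baselineAC", "baselineSqCC", "baselineNormal",
              "levelNeutral", "levelGain", "levelAmp", "role",
              "intendedFailure")]
}

# internal: clone grid GRanges for a config
.cloneGrid <- function(cfg) {
    starts <- (seq_len(cfg$nClones) - 1L) * cfg$cloneSpacingBp
    ends <- pmin(starts + cfg$cloneLengthBp, cfg$chromLengthBp)
    .bpGRanges(cfg$chrom, starts, ends,
               sprintf("clone_%04d", seq_len(cfg$nClones)))
}

#' Simulate aCGH cohorts with planted ground truth
#'
#' Draws, for every sample of every aCGH cohort, carrier status for each
#' planted region of its cohort (exact carrier counts,
#' `round(fraction * n)`, assigned by seeded sampling, with
#' `round(ampCarrierFraction * nCarriers)` of the carriers at
#' amplification level), builds the true piecewise-constant log2 signal,
#' and adds per-replicate Gaussian noise. A configurable fraction of
#' clones per sample receives inflated replicate SD or sub-threshold SNR
#' to exercise quality control. Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `profiles` (named list of [AcghProfile-class]),
#'   `cohorts` (named factor per sample), and `truth` (list with
#'   `regions`, per-sample `carrierLevel` matrices, true per-clone
#'   `states` matrices, the `genes` table and `differentialRegions`).
#' @export
simulateCohorts <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    grid <- .cloneGrid(config)
    gridStart <- start(grid) - 1L
    gridEnd <- end(grid)
    regions <- config$plantedRegions
    profiles <- list()
    cohortLabels <- character(0)
    carrierLevel <- list()
    carrierMagnitude <- list()
    trueStates <- list()
    for (co in names(config$nSamples)) {
        n <- config$nSamples[[co]]
        reg <- regions[regions$cohort == co, , drop = FALSE]
        lev <- matrix(0L, nrow = n, ncol = nrow(reg),
                      dimnames = list(NULL, reg$name))
        mag <- matrix(1, nrow = n, ncol = nrow(reg),
                      dimnames = list(NULL, reg$name))
        for (r in seq_len(nrow(reg))) {
            nC <- round(reg$carrierFraction[r] * n)
            carriers <- sample.int(n, nC)
            nAmp <- round(reg$ampCarrierFraction[r] * nC)
            lev[carriers, r] <- 1L
            if (nAmp > 0) lev[carriers[seq_len(nAmp)], r] <- 2L
            if (nC > 0 && config$heterogeneity > 0)
                mag[carriers, r] <- stats::runif(nC,
                                                 1 - config$heterogeneity,
                                                 1 + config$heterogeneity)
        }
        noiseSd <- config$probeNoiseSd *
            if (co == "CIS") config$cisNoiseMultiplier else 1
        st <- matrix(0L, nrow = config$nClones, ncol = n)
        for (s in seq_len(n)) {
            signal <- numeric(config$nClones)
            for (r in seq_len(nrow(reg))) {
                if (lev[s, r] == 0L) next
                inReg <- gridStart < reg$end[r] & gridEnd > reg$start[r]
                shift <- (if (lev[s, r] == 2L) config$ampLog2Shift
                          else reg$meanLog2Shift[r]) * mag[s, r]
                signal[inReg] <- signal[inReg] + reg$state[r] * shift
                st[inReg, s] <- reg$state[r]
            }
            k <- config$nReplicateSpots
            reps <- signal + matrix(stats::rnorm(config$nClones * k,
                                                 0, noiseSd),
                                    config$nClones, k)
            snr <- pmax(stats::rnorm(config$nClones, 20, 4), 3.1)
            nFail <- round(config$qcFailFraction * config$nClones)
            if (nFail > 0) {
                failIdx <- sample.int(config$nClones, nFail)
                sdIdx <- failIdx[seq_len(nFail %/% 2L)]
                snrIdx <- setdiff(failIdx, sdIdx)
                if (length(sdIdx))
                    reps[sdIdx, ] <- signal[sdIdx] +
                        matrix(stats::rnorm(length(sdIdx) * k, 0, 0.25),
                               length(sdIdx), k)
                if (length(snrIdx))
                    snr[snrIdx] <- stats::runif(length(snrIdx), 1, 2.9)
            }
            nm <- sprintf("%s_%02d", co, s)
            profiles[[nm]] <- AcghProfile(
                sampleName = nm,
                cloneId = grid$cloneId,
                chrom = rep(config$chrom, config$nClones),
                start = gridStart, end = gridEnd,
                replicates = reps, snr = snr)
            cohortLabels[nm] <- co
        }
        colnamesSt <- sprintf("%s_%02d", co, seq_len(n))
        dimnames(st) <- list(grid$cloneId, colnamesSt)
        rownames(lev) <- rownames(mag) <- colnamesSt
        carrierLevel[[co]] <- lev
        carrierMagnitude[[co]] <- mag
        trueStates[[co]] <- st
    }
    diffReg <- .trueDifferentialRegions(config)
    list(profiles = profiles,
         cohorts = factor(cohortLabels, levels = names(config$nSamples)),
         truth = list(regions = regions, carrierLevel = carrierLevel,
                      carrierMagnitude = carrierMagnitude,
                      states = trueStates, genes = config$genes,
                      differentialRegions = diffReg))
}

# internal: regions truly differential between AC and SqCC under the
# configured carrier fractions and the pipeline's own frequency filters
.trueDifferentialRegions <- function(cfg) {
    reg <- cfg$plantedRegions
    spans <- unique(reg[reg$cohort %in% c("AC", "SqCC"),
                        c("start", "end"), drop = FALSE])
    rows <- lapply(seq_len(nrow(spans)), function(i) {
        sub <- reg[reg$start == spans$start[i] & reg$end == spans$end[i] &
                   reg$cohort %in% c("AC", "SqCC"), , drop = FALSE]
        f <- function(co, stt) {
            r <- sub[sub$cohort == co & sub$state == stt, , drop = FALSE]
            if (nrow(r)) r$carrierFraction[1L] else 0
        }
        for (stt in c(1L, -1L)) {
            fA <- f("AC", stt); fB <- f("SqCC", stt)
            if (max(fA, fB) > 0.20 && abs(fA - fB) > 0.10)
                return(data.frame(start = spans$start[i], end = spans$end[i],
                                  state = stt,
                                  direction = if (stt == 1L) "gain" else
                                      "loss",
                                  higherCohort = if (fB > fA) "SqCC" else
                                      "AC",
                                  freqAC = fA, freqSqCC = fB))
        }
        NULL
    })
    do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                     list(make.row.names = FALSE)))
}

#' Simulate expression coupled to the planted copy-number truth
#'
#' Expression (log10 scale) for every gene of the configured panel in the
#' AC-like and SqCC-like tumor samples plus an expression-only normal
#' cohort. For linearly coupled genes,
#' `expression = cohort baseline + dosageSlope x (the sample's measured
#' mean combined log2 over the gene interval) + Normal(0, exprNoiseSd)`,
#' so expression tracks the gene dosage actually present in each tumor
#' (including the heterogeneity scalar); level-mapped genes read their
#' expression off the sample's carrier level; constant genes ignore
#' dosage. Normal samples express each gene at its normal baseline.
#'
#' @param config the [simulationConfig()] used for [simulateCohorts()].
#' @param sim result of [simulateCohorts()] under the same config.
#' @return an [ExpressionPanel-class] with cohorts AC, SqCC and normal.
#' @export
simulateExpression <- function(config, sim) {
    stopifnot(inherits(config, "SimulationConfig"))
    truth <- sim$truth
    genes <- config$genes
    tumorCohorts <- intersect(c("AC", "SqCC"), names(config$nSamples))
    sampleNames <- unlist(lapply(tumorCohorts, function(co)
        colnames(truth$states[[co]])), use.names = FALSE)
    if (!all(sampleNames %in% names(sim$profiles)))
        stop("truth/profile sample mismatch")
    set.seed(config$seed + 1L)
    reg <- truth$regions
    grid <- .cloneGrid(config)
    gridStart <- start(grid) - 1L
    gridEnd <- end(grid)
    # measured mean combined log2 over each gene interval, per sample
    geneClones <- lapply(seq_len(nrow(genes)), function(g)
        which(gridStart < genes$end[g] & gridEnd > genes$start[g]))
    measuredDose <- function(sampleName) {
        lr <- rowMeans(sim$profiles[[sampleName]]@replicates)
        vapply(geneClones, function(ix) mean(lr[ix]), numeric(1))
    }
    # carrier level of the region covering a gene, per cohort sample
    geneLevel <- function(g, co) {
        lev <- truth$carrierLevel[[co]]
        sub <- reg[reg$cohort == co & reg$start < genes$end[g] &
                   reg$end > genes$start[g], , drop = FALSE]
        if (nrow(sub)) lev[, sub$name[1L]] else integer(nrow(lev))
    }
    cols <- list()
    cohortOut <- character(0)
    for (co in tumorCohorts) {
        nmv <- colnames(truth$states[[co]])
        dose <- vapply(nmv, measuredDose, numeric(nrow(genes)))
        vals <- matrix(NA_real_, nrow(genes), length(nmv))
        for (g in seq_len(nrow(genes))) {
            base <- switch(genes$type[g],
                linear = (if (co == "AC") genes$baselineAC[g]
                          else genes$baselineSqCC[g]) +
                         genes$slope[g] * config$dosageSlope * dose[g, ],
                levels = {
                    lv <- geneLevel(g, co)
                    ifelse(lv == 2L, genes$levelAmp[g],
                    ifelse(lv == 1L, genes$levelGain[g],
                           genes$levelNeutral[g]))
                },
                constant = rep(if (co == "AC") genes$baselineAC[g]
                               else genes$baselineSqCC[g], length(nmv)),
                stop("unknown gene type '", genes$type[g], "'"))
            vals[g, ] <- base + stats::rnorm(length(nmv), 0,
                                             config$exprNoiseSd)
        }
        colnames(vals) <- nmv
        cols[[co]] <- vals
        cohortOut <- c(cohortOut, rep(co, length(nmv)))
    }
    normal <- matrix(genes$baselineNormal, nrow(genes), config$nNormal) +
        matrix(stats::rnorm(nrow(genes) * config$nNormal, 0,
                            config$exprNoiseSd),
               nrow(genes), config$nNormal)
    colnames(normal) <- sprintf("normal_%02d", seq_len(config$nNormal))
    exprs <- cbind(do.call(cbind, cols), normal)
    rownames(exprs) <- paste0("p_", genes$gene)
    cohortOut <- c(cohortOut, rep("normal", config$nNormal))
    probeMap <- data.frame(probeId = paste0("p_", genes$gene),
                           gene = genes$gene, chrom = genes$chrom,
                           start = genes$start, end = genes$end)
    ExpressionPanel(exprs, probeMap, cohortOut, scale = "log10")
}

#' Simulate a null StateMatrix for calibration
#'
#' States drawn i.i.d. per clone and sample from the same gain/loss/neutral
#' distribution in both cohorts (no planted differences); adjacent clones
#' are independent, so the disparity pipeline sees about one region per
#' clone. Used to check the type-I behaviour of [compareCohorts()].
#'
#' @param nClones number of clones (default 500).
#' @param nPerCohort named length-2 vector of cohort sizes
#'   (default `c(A = 50, B = 50)`).
#' @param pGain,pLoss per-entry gain and loss probabilities (default 0.15
#'   each).
#' @param cloneSpacingBp spacing (default 80,000).
#' @param seed integer seed.
#' @return a [StateMatrix-class].
#' @export
simulateNullStateMatrix <- function(nClones = 500,
                                    nPerCohort = c(A = 50, B = 50),
                                    pGain = 0.15, pLoss = 0.15,
                                    cloneSpacingBp = 80000, seed = 1) {
    stopifnot(length(nPerCohort) == 2L, pGain + pLoss < 1)
    set.seed(seed)
    n <- sum(nPerCohort)
    st <- matrix(sample(c(1L, -1L, 0L), nClones * n, replace = TRUE,
                        prob = c(pGain, pLoss, 1 - pGain - pLoss)),
                 nClones, n)
    colnames(st) <- sprintf("s_%03d", seq_len(n))
    starts <- (seq_len(nClones) - 1L) * cloneSpacingBp
    grid <- .bpGRanges("chr8", starts, starts + cloneSpacingBp,
                       sprintf("clone_%04d", seq_len(nClones)))
    new("StateMatrix", states = st, clones = grid,
        cohorts = factor(rep(names(nPerCohort), nPerCohort)),
        observed = matrix(TRUE, nClones, n))
}
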